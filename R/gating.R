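#' Point-in-polygon membership (even-odd rule, boundary inclusive)
#'
#' Ray-crossing test with an explicit on-edge check so that droplets lying
#' exactly on a gate boundary count as inside (the convention used when
#' gates are drawn manually on dot plots).
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param polygon Numeric matrix with two columns (vertices in order; the
#'   closing edge is implicit). Must have >= 3 vertices and be simple.
#' @return Logical vector: `TRUE` when the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    .stopf("polygon must be a matrix of >= 3 vertices in 2 columns")
  }
  if (any(!is.finite(polygon))) .stopf("polygon vertices must be finite")
  px <- polygon[, 1]; py <- polygon[, 2]
  nv <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  scale <- max(abs(polygon), 1)
  tol <- 1e-9 * scale
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # boundary test: collinear and within the segment's bounding box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_seg <- abs(cross) <= tol * max(abs(xj - xi) + abs(yj - yi), 1) &
      x >= pmin(xi, xj) - tol & x <= pmax(xi, xj) + tol &
      y >= pmin(yi, yj) - tol & y <= pmax(yi, yj) + tol
    on_edge <- on_edge | on_seg
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Derive polygonal gates from a positive-control chamber
#'
#' Reproduces, automatically, what an operator does on the instrument
#' software: place one polygon per expected cluster on the 2D dot plots,
#' anchored on the positions of the positive-control clusters. Per-channel
#' negative and positive levels are estimated from the control, and each
#' detection class of the design gets a rectangular polygon on its plane
#' whose bounds sit at 15% (negative side) and 45% (positive side) of the
#' negative-to-positive gap, leaving the intermediate "rain" band
#' unclassified: attenuated droplets neither re-enter a negative axis
#' region nor count as positive unless they remain close to the cluster.
#' The positive bound is deliberately permissive (45% rather than midway)
#' because duplication clusters sit at distinct, partially attenuated HEX
#' positions.
#'
#' Gate placement is affine-equivariant: rescaling all intensities and
#' re-deriving from the rescaled control yields the same classification.
#'
#' @param control A `droplet_set` from a positive-control chamber
#'   containing every positive cluster of the design (wild-type plus all
#'   mutant classes).
#' @param design An `assay_design`.
#' @return An object of class `gate_set`: gates (name, plane, polygon),
#'   per-channel baseline thresholds, and the precedence order.
#' @export
derive_gates <- function(control, design) {
  stopifnot(inherits(control, "droplet_set"))
  validate_assay_design(design)
  channels_used <- unique(design$probes$channel)
  levels <- list()
  for (ch in channels_used) {
    v <- control[[ch]]
    mid <- (min(v) + max(v)) / 2
    neg_vals <- v[v <= mid]
    pos_vals <- v[v > mid]
    if (!length(pos_vals) || !length(neg_vals)) {
      .stopf("control chamber has no separated positive cluster on channel %s", ch)
    }
    neg <- stats::median(neg_vals)
    pos <- stats::median(pos_vals)
    # a real positive cluster must sit well clear of the negative spread
    if ((pos - neg) < 6 * max(stats::mad(neg_vals), 1e-12)) {
      .stopf("control chamber has no separated positive cluster on channel %s", ch)
    }
    levels[[ch]] <- c(neg = neg, pos = pos)
  }
  span <- vapply(channels_used,
                 function(ch) diff(range(control[[ch]])), numeric(1))
  names(span) <- channels_used
  gates <- list()
  for (g in design$gate_defs) {
    lo <- hi <- numeric(2)
    for (i in 1:2) {
      ch <- g$plane[i]
      neg <- levels[[ch]][["neg"]]; pos <- levels[[ch]][["pos"]]
      gap <- pos - neg
      pad <- 0.5 * gap
      bounds <- switch(g$axis_state[i],
                       "+" = c(neg + 0.45 * gap, max(control[[ch]]) + pad),
                       "-" = c(min(control[[ch]]) - pad, neg + 0.15 * gap),
                       # mid band: attenuated clusters (duplications) sit
                       # between the negatives and the full-amplitude
                       # clusters; the upper bound excludes co-occupancy
                       # droplets at full amplitude
                       "m" = c(neg + 0.30 * gap, neg + 0.90 * gap),
                       "*" = c(min(control[[ch]]) - pad, max(control[[ch]]) + pad),
                       .stopf("unknown axis state '%s'", g$axis_state[i]))
      lo[i] <- bounds[1]; hi[i] <- bounds[2]
    }
    poly <- cbind(c(lo[1], hi[1], hi[1], lo[1]), c(lo[2], lo[2], hi[2], hi[2]))
    colnames(poly) <- g$plane
    gates[[g$name]] <- list(name = g$name, plane = g$plane, polygon = poly,
                            signature = g$signature)
  }
  gs <- structure(list(design = design$name,
                       channels = channels_used,
                       baseline = vapply(channels_used, function(ch) {
                         levels[[ch]][["neg"]] +
                           0.15 * (levels[[ch]][["pos"]] - levels[[ch]][["neg"]])
                       }, numeric(1)),
                       gates = gates,
                       precedence = design$precedence),
                  class = "gate_set")
  names(gs$baseline) <- channels_used
  # every expected cluster must be present in the control; a handful of
  # stray droplets (noise, co-occupancy) does not constitute a cluster
  cc <- classify_droplets(control, gs)
  min_count <- max(10, ceiling(5e-4 * cc$total_partitions))
  empty_gates <- names(cc$counts)[cc$counts < min_count]
  if (length(empty_gates)) {
    .stopf("positive control is missing cluster(s) for class(es): %s",
           paste(empty_gates, collapse = ", "))
  }
  gs
}

#' Classify droplets with a gate set
#'
#' Tests every droplet for membership (boundary counts as inside) in every
#' gate. Gate counts are tallied independently per gate -- so a droplet in
#' the wild-type gate on the FAM-Cy5 plane and in the duplication gate on
#' the FAM-HEX plane contributes to both, exactly as on the instrument's
#' per-plane dot plots; [correct_dup_overlap()] removes that double count.
#' For droplet-conservation accounting each droplet is also resolved to a
#' single class using the precedence order; droplets in no gate are
#' `empty` when below baseline in every channel and `unclassified` (rain)
#' otherwise.
#'
#' @param ds A `droplet_set`.
#' @param gates A `gate_set` from [derive_gates()] or [read_gates()].
#' @return An object of class `cluster_counts`: `counts` (per-gate droplet
#'   counts), `assigned` (per-droplet precedence-resolved class),
#'   `n_classified`, `unclassified`, `n_empty`, `total_partitions`, and the
#'   chamber geometry.
#' @export
classify_droplets <- function(ds, gates) {
  stopifnot(inherits(ds, "droplet_set"), inherits(gates, "gate_set"))
  missing_ch <- setdiff(gates$channels, names(ds))
  if (length(missing_ch)) {
    .stopf("droplet set lacks channel(s): %s", paste(missing_ch, collapse = ", "))
  }
  n <- nrow(ds)
  hits <- matrix(FALSE, nrow = n, ncol = length(gates$gates),
                 dimnames = list(NULL, names(gates$gates)))
  for (g in gates$gates) {
    hits[, g$name] <- point_in_polygon(ds[[g$plane[1]]], ds[[g$plane[2]]],
                                       g$polygon)
  }
  counts <- colSums(hits)
  prec <- intersect(gates$precedence, colnames(hits))
  assigned <- rep(NA_character_, n)
  for (g in rev(prec)) assigned[hits[, g]] <- g
  below <- rep(TRUE, n)
  for (ch in gates$channels) below <- below & ds[[ch]] <= gates$baseline[[ch]]
  is_empty <- is.na(assigned) & below
  unclassified <- sum(is.na(assigned) & !below)
  structure(list(chamber_id = unique(ds$chamber_id),
                 total_partitions = attr(ds, "n_partitions") %||% n,
                 counts = counts,
                 assigned = assigned,
                 n_classified = sum(!is.na(assigned)),
                 n_empty = sum(is_empty),
                 unclassified = unclassified,
                 droplet_volume = attr(ds, "droplet_volume"),
                 reaction_volume = attr(ds, "reaction_volume"),
                 design = gates$design,
                 dup_corrected = FALSE),
            class = "cluster_counts")
}

#' @export
print.cluster_counts <- function(x, ...) {
  cat(sprintf("<cluster_counts '%s': %d partitions, %d classified, %d rain, %d empty%s>\n",
              paste(x$chamber_id, collapse = "+"), x$total_partitions,
              x$n_classified, x$unclassified, x$n_empty,
              if (x$dup_corrected) ", dup-corrected" else ""))
  print(x$counts)
  invisible(x)
}

#' Correct the duplication/wild-type gate superposition
#'
#' Duplication-bearing droplets light the drop-off, duplication and
#' reference probes simultaneously (FAM+HEX+Cy5+), so on the FAM-Cy5 dot
#' plot they fall inside the wild-type gate and are double counted. The
#' correction removes the duplication-gate count from the wild-type tally
#' so that no droplet contributes to both classes; the duplication count
#' itself is unchanged. The corrected wild-type count is floored at zero
#' (with a warning), which can only trigger on pathological inputs.
#'
#' @param raw A `cluster_counts` containing both a `WT` gate and a
#'   duplication gate.
#' @param wt,dup Names of the wild-type and duplication gates.
#' @return The corrected `cluster_counts` (flag `dup_corrected` set).
#' @examples
#' # WT gate 5000, dup gate 100 -> WT 4900, dup 100
#' @export
correct_dup_overlap <- function(raw, wt = "WT",
                                dup = "Y772_A775dup-G778_P780dup") {
  stopifnot(inherits(raw, "cluster_counts"))
  if (raw$dup_corrected) return(raw)
  if (!wt %in% names(raw$counts) || !dup %in% names(raw$counts)) {
    .stopf("counts must contain both '%s' and '%s' gates", wt, dup)
  }
  corrected <- raw$counts[[wt]] - raw$counts[[dup]]
  if (corrected < 0) {
    .warnf("duplication gate (%d) exceeds WT gate (%d); flooring WT at 0",
           raw$counts[[dup]], raw$counts[[wt]])
    corrected <- 0
  }
  raw$counts[[wt]] <- corrected
  raw$dup_corrected <- TRUE
  raw
}

#' Serialize gate sets as JSON
#'
#' Gates are versioned run inputs: manually drawn gate files are
#' first-class and interchangeable with [derive_gates()] output.
#'
#' @param gates A `gate_set`.
#' @param path Output path.
#' @return `write_gates()` returns `path` invisibly; `read_gates()`
#'   returns a `gate_set`.
#' @export
write_gates <- function(gates, path) {
  stopifnot(inherits(gates, "gate_set"))
  out <- list(format = "dropscreen-gates/1",
              design = gates$design,
              channels = gates$channels,
              baseline = as.list(gates$baseline),
              precedence = gates$precedence,
              gates = lapply(unname(gates$gates), function(g) {
                list(name = g$name, plane = g$plane,
                     signature = g$signature,
                     polygon = apply(g$polygon, 1, as.numeric, simplify = FALSE))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$format, "dropscreen-gates/1")) {
    .stopf("unrecognised gate file format in '%s'", path)
  }
  gates <- list()
  for (g in raw$gates) {
    poly <- do.call(rbind, lapply(g$polygon, unlist))
    plane <- unlist(g$plane)
    colnames(poly) <- plane
    gates[[g$name]] <- list(name = g$name, plane = plane, polygon = poly,
                            signature = g$signature)
  }
  structure(list(design = raw$design,
                 channels = unlist(raw$channels),
                 baseline = unlist(raw$baseline),
                 gates = gates,
                 precedence = unlist(raw$precedence)),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("<gate_set for '%s': %d gates on channels %s>\n", x$design,
              length(x$gates), paste(x$channels, collapse = "/")))
  for (g in x$gates) {
    cat(sprintf("  %-28s %s x %s\n", g$name, g$plane[1], g$plane[2]))
  }
  invisible(x)
}
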