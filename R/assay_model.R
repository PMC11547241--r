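#' Load the packaged ERBB2 assay definitions
#'
#' Reads the assay-definition file shipped with the package and returns the
#' multiplex ERBB2 screening design (`ERBB2_S`) together with the six
#' confirmatory wild-type/mutant (WT-MUT) duplex designs. The screening
#' design amplifies four amplicons and reads them out in five detection
#' groups: `WT`, `S310F/Y` (FAM), `L755S-D769H/Y-L869R` (HEX),
#' `Y772_A775dup-G778_P780dup` (HEX, in association with the drop-off and
#' reference probes) and the drop-off hotspot group `776-779_MUT`
#' (Cy5-only). Assay definitions are data, not code: a custom file in the
#' same JSON format can be supplied to analyse other designs.
#'
#' The 17-variant membership list packaged here is reconstructed from the
#' published assay description (the enumerated point mutations and
#' insertions plus the most frequent codon 776-779 hotspot substitutions);
#' it is flagged as such in the definition file.
#'
#' @param file Path to an assay-definition JSON file. Defaults to the
#'   definitions shipped in `inst/extdata/erbb2_assays.json`.
#'
#' @return A list of class `assay_panel` with elements:
#' \describe{
#'   \item{screening}{`assay_design` object for the screening multiplex.}
#'   \item{duplexes}{Named list of `assay_design` objects, one per WT-MUT
#'     duplex.}
#'   \item{variants}{Data frame of detectable variants (`id`, `protein`,
#'     `cdna`, `group`).}
#'   \item{aliases}{Named character vector mapping legacy variant names to
#'     recommended protein-level names.}
#' }
#' @examples
#' assays <- build_erbb2_assays()
#' length(assays$screening$amplicons)  # 4 amplicons
#' names(assays$duplexes)
#' @export
build_erbb2_assays <- function(file = system.file("extdata", "erbb2_assays.json",
                                                  package = "dropscreen")) {
  if (!nzchar(file) || !file.exists(file)) {
    .stopf("assay definition file not found: '%s'", file)
  }
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!identical(raw$format, "dropscreen-assay/1")) {
    .stopf("unrecognised assay definition format: '%s'", raw$format %||% "<missing>")
  }
  variants <- do.call(rbind, lapply(raw$variants, function(v) {
    data.frame(id = v$id, protein = v$protein, cdna = v$cdna, group = v$group,
               stringsAsFactors = FALSE)
  }))
  aliases <- unlist(raw$aliases)
  screening <- .as_assay_design(raw$screening, variants)
  duplexes <- lapply(raw$duplexes, .as_assay_design, variants = variants)
  names(duplexes) <- vapply(duplexes, `[[`, character(1), "name")
  panel <- list(screening = screening, duplexes = duplexes,
                variants = variants, aliases = aliases)
  class(panel) <- "assay_panel"
  validate_assay_design(screening)
  for (d in duplexes) validate_assay_design(d)
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an assay_design object from the parsed JSON representation.
.as_assay_design <- function(x, variants) {
  probes <- do.call(rbind, lapply(x$amplicons, function(a) {
    do.call(rbind, lapply(a$probes, function(p) {
      data.frame(name = p$name, channel = p$channel, role = p$role,
                 amplicon = a$id, stringsAsFactors = FALSE)
    }))
  }))
  binds <- list()
  for (a in x$amplicons) {
    for (p in a$probes) binds[[p$name]] <- unlist(p$binds)
  }
  groups <- lapply(x$groups, function(g) {
    list(name = g$name,
         members = unlist(g$members) %||% character(0),
         duplexes = unlist(g$duplexes) %||% character(0))
  })
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  gates <- lapply(x$gates, function(g) {
    list(name = g$name, plane = unlist(g$plane),
         axis_state = unlist(g$axis_state), signature = g$signature)
  })
  design <- list(
    name = x$name,
    type = x$type,
    channels = unlist(x$channels),
    amplicons = lapply(x$amplicons, function(a) {
      list(id = a$id, codon_range = unlist(a$codon_range),
           probes = vapply(a$probes, `[[`, character(1), "name"))
    }),
    probes = probes,
    binds = binds,
    groups = groups,
    decode = unlist(x$decode),
    gate_defs = gates,
    precedence = unlist(x$precedence),
    fp_rate = unlist(x$fp_rate)
  )
  class(design) <- "assay_design"
  design
}

#' Validate an assay design
#'
#' Checks the structural invariants of an `assay_design`: channels are a
#' subset of FAM/HEX/Cy5, every probe binds at least one template, drop-off
#' and reference probes share an amplicon, the decode table is total over
#' the eight FAM/HEX/Cy5 boolean signatures, each non-WT detection group is
#' non-empty, and no variant belongs to two non-WT groups.
#'
#' @param design An `assay_design` object.
#' @return The design, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_assay_design <- function(design) {
  if (!inherits(design, "assay_design")) .stopf("not an assay_design object")
  if (!all(design$channels %in% c("FAM", "HEX", "Cy5"))) {
    .stopf("design '%s': channels must be among FAM, HEX, Cy5", design$name)
  }
  if (!all(design$probes$channel %in% c("FAM", "HEX", "Cy5"))) {
    .stopf("design '%s': every probe needs a single valid channel", design$name)
  }
  for (p in design$probes$name) {
    if (length(design$binds[[p]]) < 1L) {
      .stopf("design '%s': probe '%s' binds no template", design$name, p)
    }
  }
  do <- design$probes[design$probes$role == "drop-off", , drop = FALSE]
  ref <- design$probes[design$probes$role == "reference", , drop = FALSE]
  if (nrow(do) > 0 && nrow(ref) > 0 &&
      !any(ref$amplicon %in% do$amplicon)) {
    .stopf("design '%s': drop-off and reference probes must share an amplicon",
           design$name)
  }
  sigs <- apply(expand.grid(0:1, 0:1, 0:1), 1L,
                function(b) paste0(b[1], b[2], b[3]))
  missing <- setdiff(sigs, names(design$decode))
  if (length(missing)) {
    .stopf("design '%s': decode table misses signature(s) %s",
           design$name, paste(missing, collapse = ", "))
  }
  nonwt <- design$groups[names(design$groups) != "WT"]
  members <- unlist(lapply(nonwt, `[[`, "members"))
  if (any(duplicated(members))) {
    .stopf("design '%s': variant(s) %s belong to more than one non-WT group",
           design$name, paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (any(vapply(nonwt, function(g) length(g$members) == 0L, logical(1)))) {
    .stopf("design '%s': empty non-WT detection group", design$name)
  }
  invisible(design)
}

#' Build a three-channel cluster signature
#'
#' @param fam,hex,cy5 Logical; whether the droplet is positive in the
#'   corresponding channel.
#' @param amplicon_context Amplicon id the signature is interpreted in
#'   (used to check that the signature is addressed to the right design).
#' @return An object of class `cluster_signature`.
#' @examples
#' cluster_signature(fam = TRUE, hex = FALSE, cy5 = TRUE, "ERBB2_772_780")
#' @export
cluster_signature <- function(fam, hex, cy5, amplicon_context) {
  stopifnot(is.logical(fam), is.logical(hex), is.logical(cy5),
            length(fam) == 1L, length(hex) == 1L, length(cy5) == 1L)
  structure(list(fam = fam, hex = hex, cy5 = cy5,
                 amplicon_context = amplicon_context),
            class = "cluster_signature")
}

.signature_key <- function(fam, hex, cy5) {
  paste0(as.integer(fam), as.integer(hex), as.integer(cy5))
}

#' Decode a cluster signature into a detection-class label
#'
#' Applies the design's three-color truth table. For the screening design
#' the six canonical cases of the 772-780 amplicon decode as: FAM+Cy5+ is
#' `WT`; Cy5+ alone is `776-779_MUT`; HEX+Cy5+ is `776-779_MUT+dup`; and
#' FAM+HEX+Cy5+ is the duplication group `Y772_A775dup-G778_P780dup`
#' (either duplication, or both -- identity is deferred to the duplex
#' step). Signatures produced by the mutation-specific FAM and HEX probe
#' groups decode to their group labels.
#'
#' @param sig A `cluster_signature`.
#' @param design An `assay_design`.
#' @return A detection-class label (character scalar).
#' @examples
#' design <- build_erbb2_assays()$screening
#' decode_signature(cluster_signature(TRUE, FALSE, TRUE, "ERBB2_772_780"), design)  # "WT"
#' decode_signature(cluster_signature(FALSE, FALSE, TRUE, "ERBB2_772_780"), design) # "776-779_MUT"
#' @export
decode_signature <- function(sig, design) {
  if (!inherits(sig, "cluster_signature")) .stopf("sig must be a cluster_signature")
  validate_assay_design(design)
  amp_ids <- vapply(design$amplicons, `[[`, character(1), "id")
  if (!sig$amplicon_context %in% amp_ids) {
    .stopf("amplicon context '%s' is not part of assay '%s' (has: %s); mis-specified assay?",
           sig$amplicon_context, design$name, paste(amp_ids, collapse = ", "))
  }
  unname(design$decode[[.signature_key(sig$fam, sig$hex, sig$cy5)]])
}

#' Normalize a variant name to recommended nomenclature
#'
#' Duplication variants in particular circulate under legacy insertion
#' names (e.g. `A775-G776insYVMA` for `Y772_A775dup`, `P780_Y781insGSP`
#' for `G778_P780dup`). Lookup is case-insensitive, tolerates a leading
#' `p.`, and is idempotent: canonical names map to themselves.
#'
#' @param alias Variant name or legacy alias (non-empty character scalar).
#' @param panel An `assay_panel`, as returned by [build_erbb2_assays()].
#' @return A list of class `mutation_id` with `protein_name`, `cdna_name`
#'   (all cDNA-level annotations sharing the protein name) and `aliases`.
#' @examples
#' normalize_variant_name("A775-G776insYVMA")$protein_name  # "Y772_A775dup"
#' normalize_variant_name("p.l755s")$protein_name           # "L755S"
#' @export
normalize_variant_name <- function(alias, panel = build_erbb2_assays()) {
  if (!is.character(alias) || length(alias) != 1L || !nzchar(trimws(alias))) {
    .stopf("alias must be a non-empty character scalar")
  }
  key <- tolower(sub("^p\\.", "", trimws(alias)))
  proteins <- unique(panel$variants$protein)
  lut <- c(stats::setNames(proteins, tolower(proteins)),
           stats::setNames(unname(panel$aliases),
                           tolower(sub("^p\\.", "", names(panel$aliases)))))
  if (!key %in% names(lut)) {
    .stopf("unrecognised variant name '%s'; known names: %s", alias,
           paste(sort(unique(c(proteins, names(panel$aliases)))), collapse = ", "))
  }
  protein <- unname(lut[[key]])
  rows <- panel$variants[panel$variants$protein == protein, , drop = FALSE]
  known_aliases <- names(panel$aliases)[panel$aliases == protein]
  structure(list(protein_name = protein,
                 cdna_name = rows$cdna,
                 aliases = known_aliases),
            class = "mutation_id")
}

#' @export
print.mutation_id <- function(x, ...) {
  cat(x$protein_name,
      if (length(x$cdna_name)) paste0(" (", paste(x$cdna_name, collapse = "; "), ")"),
      "\n", sep = "")
  if (length(x$aliases)) cat("aliases:", paste(x$aliases, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay_design '%s' (%s): %d amplicons, %d probes, %d groups>\n",
              x$name, x$type, length(x$amplicons), nrow(x$probes),
              length(x$groups)))
  invisible(x)
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel: screening '%s' + %d duplexes; %d variants>\n",
              x$screening$name, length(x$duplexes), nrow(x$variants)))
  invisible(x)
}

# Template species a design can see (wild-type plus all group members).
.design_templates <- function(design) {
  unique(c("WT", unlist(lapply(design$groups, `[[`, "members"))))
}

# Detection-class labels of the non-WT groups of a design.
.mutant_groups <- function(design) {
  setdiff(names(design$groups), "WT")
}

# Per-channel signal level a droplet containing exactly `template` shows
# under this design (max probe amplitude scale per channel).
.canonical_levels <- function(design, template) {
  lvl <- c(FAM = 0, HEX = 0, Cy5 = 0)
  for (p in design$probes$name) {
    b <- design$binds[[p]]
    if (template %in% names(b)) {
      ch <- design$probes$channel[design$probes$name == p]
      lvl[ch] <- max(lvl[ch], b[[template]])
    }
  }
  lvl
}

# Map each of the 8 signatures to the set of gate names a correctly gated
# droplet with that true signature may resolve to (used as the provenance
# oracle when scoring classification accuracy). A mid-band ("m") axis is
# treated as positive at the boolean level.
.expected_gates_by_signature <- function(design) {
  out <- list()
  sigs <- c("000", "100", "010", "001", "110", "101", "011", "111")
  for (s in sigs) {
    bits <- as.integer(strsplit(s, "")[[1]]) == 1L
    names(bits) <- c("FAM", "HEX", "Cy5")
    hit <- character(0)
    for (g in design$gate_defs) {
      ok <- TRUE
      for (i in seq_along(g$plane)) {
        st <- g$axis_state[i]
        if (st %in% c("+", "m") && !bits[[g$plane[i]]]) ok <- FALSE
        if (st == "-" && bits[[g$plane[i]]]) ok <- FALSE
      }
      if (ok) hit <- c(hit, g$name)
    }
    out[[s]] <- hit
  }
  out
}
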