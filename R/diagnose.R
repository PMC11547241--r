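#' Plan dilution and replication for a cfDNA sample
#'
#' Applies the input rules of the workflow: the 15 uL cfDNA input may
#' carry at most 33 ng (10,000 copies/PCR at 3.3 pg per haploid genome
#' equivalent), so concentrated samples are diluted; low-concentration
#' samples are assayed in up to three replicates so that at least 10 ng
#' are investigated in total, material permitting.
#'
#' @param cfdna_ng_per_ul cfDNA concentration of the (undiluted) eluate in
#'   ng/uL.
#' @param available_ul Eluate volume available (uL); `Inf` for unlimited.
#' @param input_volume Input per PCR in uL.
#' @param max_ng_per_pcr Input cap per reaction in ng.
#' @param min_total_ng Minimum total mass to investigate across
#'   replicates.
#' @param max_replicates Replicate ceiling.
#' @param pg_per_copy Mass of one haploid genome equivalent in pg.
#' @return A list of class `reaction_plan`: `dilution_factor`,
#'   `n_replicates`, `input_ng_per_pcr`, `projected_copies_per_pcr`,
#'   `total_ng_assayed`.
#' @examples
#' plan_reaction(66 / 15)$dilution_factor          # 2
#' plan_reaction(4 / 15)$n_replicates              # 3 (12 ng >= 10 ng)
#' @export
plan_reaction <- function(cfdna_ng_per_ul, available_ul = Inf,
                          input_volume = 15, max_ng_per_pcr = 33,
                          min_total_ng = 10, max_replicates = 3L,
                          pg_per_copy = 3.3) {
  if (cfdna_ng_per_ul < 0 || available_ul < 0) {
    .stopf("concentration and available volume must be >= 0")
  }
  ng_undiluted <- cfdna_ng_per_ul * input_volume
  dilution <- max(1, ng_undiluted / max_ng_per_pcr)
  ng_per_pcr <- ng_undiluted / dilution
  max_reps <- max(1L, floor(available_ul * dilution / input_volume))
  n_rep <- 1L
  while (n_rep * ng_per_pcr < min_total_ng &&
         n_rep < min(max_replicates, max_reps)) {
    n_rep <- n_rep + 1L
  }
  structure(list(dilution_factor = dilution,
                 n_replicates = n_rep,
                 input_ng_per_pcr = ng_per_pcr,
                 projected_copies_per_pcr = ng_per_pcr * 1000 / pg_per_copy,
                 total_ng_assayed = n_rep * ng_per_pcr),
            class = "reaction_plan")
}

#' Apply the replicate positivity rule to a detection group
#'
#' Positivity is decided on raw positive-droplet counts against the
#' single-replicate limits: with one replicate, a count at or above the
#' LOD95 is positive (pending confirmation), at or below the LOB95
#' negative, and in between equivocal -- the workflow then demands two
#' more replicates. With several replicates, a group is positive when at
#' least two replicates reach the LOD95, negative when all are at or
#' below the LOB95, and equivocal otherwise.
#'
#' @param replicate_counts Integer vector of per-replicate raw
#'   positive-droplet counts (>= 1 replicate).
#' @param limits Either a one-row subset of a `limit_estimates` table for
#'   the group, or a numeric vector `c(lob = ..., lod = ...)`.
#' @param group Group label carried through to the result.
#' @return A list of class `group_call`: `group`, `replicate_counts`,
#'   `status` (`"negative"`, `"equivocal"`, `"positive"`),
#'   `recommendation` (e.g. how many further replicates to run), `lob`,
#'   `lod`.
#' @examples
#' call_detection_group(c(6, 7, 2), c(lob = 3, lod = 5))$status  # "positive"
#' call_detection_group(4, c(lob = 3, lod = 8))$status           # "equivocal"
#' @export
call_detection_group <- function(replicate_counts, limits, group = NA_character_) {
  if (length(replicate_counts) < 1L) .stopf("need at least one replicate count")
  if (inherits(limits, "limit_estimates") || is.data.frame(limits)) {
    row <- if (!is.na(group) && "group" %in% names(limits)) {
      limits[limits$group == group & limits$n_replicates_assayed == 1L, , drop = FALSE]
    } else limits
    if (nrow(row) < 1L) .stopf("no limits available for group '%s'", group)
    lob <- row$lob95_droplets[1]; lod <- row$lod95_droplets[1]
  } else {
    if (!all(c("lob", "lod") %in% names(limits))) {
      .stopf("limits must provide 'lob' and 'lod'")
    }
    lob <- limits[["lob"]]; lod <- limits[["lod"]]
  }
  n <- length(replicate_counts)
  recommendation <- NA_character_
  if (n == 1L) {
    if (replicate_counts <= lob) {
      status <- "negative"
    } else if (replicate_counts >= lod) {
      status <- "positive"
      recommendation <- "confirm mutation identity with the matching duplex assay"
    } else {
      status <- "equivocal"
      recommendation <- "run 2 more replicates"
    }
  } else {
    if (sum(replicate_counts >= lod) >= 2L) {
      status <- "positive"
      recommendation <- "confirm mutation identity with the matching duplex assay"
    } else if (all(replicate_counts <= lob)) {
      status <- "negative"
    } else {
      status <- "equivocal"
      recommendation <- if (n == 2L) "run 1 more replicate" else
        "inconclusive after 3 replicates; consider more input material"
    }
  }
  structure(list(group = group, replicate_counts = replicate_counts,
                 status = status, recommendation = recommendation,
                 lob = lob, lod = lod),
            class = "group_call")
}

#' Run the two-step screen-then-identify strategy on one sample
#'
#' Step 1 screens the sample with the multiplex assay: each replicate
#' chamber is gated, the duplication/wild-type overlap corrected, and each
#' detection group called with the replicate positivity rule
#' ([call_detection_group()]). Step 2 identifies the mutation(s): for each
#' positive group the matching WT-MUT duplex chambers are gated and
#' called; positive duplexes yield the final identifications, quantified
#' (copies/PCR, copies/mL plasma, MAF) from the duplex counts. Samples
#' positive at screening whose duplexes are all negative are reported
#' `unconfirmed`; positive groups without duplex data are `incomplete`.
#'
#' Every run must carry a negative (water) and a positive control chamber;
#' calls from runs with failed controls are suppressed.
#'
#' @param screen_chambers List of `droplet_set` replicates of the
#'   screening assay for this sample.
#' @param duplex_chambers Named list (duplex name -> list of
#'   `droplet_set`) of confirmatory chambers; may be empty for negative
#'   samples.
#' @param controls List with elements `negative` and `positive`
#'   (`droplet_set` objects from the screening run's control chambers).
#' @param assays An `assay_panel` from [build_erbb2_assays()].
#' @param gates `gate_set` for the screening assay (e.g. derived from the
#'   positive control).
#' @param duplex_gates Named list of `gate_set` objects per duplex;
#'   derived from the duplex chambers' own positive controls in practice.
#' @param limits `limit_estimates` for the screening assay (single
#'   replicate rows).
#' @param duplex_limits Named list or data frame of limits per duplex
#'   (defaults to `c(lob = 2, lod = 7)`-style values computed from the
#'   duplex false-positive defaults if omitted).
#' @param mu_corr Named corrected blank means for LOB correction of
#'   screening counts (defaults to the `mu_corr` column of `limits`).
#' @param prep A [sample_prep()] for the plasma conversion (optional).
#' @param sample_id Sample identifier.
#' @return A list of class `sample_call`: `sample_id`, `controls_ok`,
#'   `status` (`"ok"`, `"invalid-controls"`, `"incomplete"`,
#'   `"unconfirmed"`, `"negative"`), `screen` (data frame of group
#'   calls), `identified` (data frame: `mutation`, `copies_per_pcr`,
#'   `copies_per_ml`, `maf_pct`).
#' @export
run_two_step <- function(screen_chambers, duplex_chambers = list(),
                         controls, assays, gates, duplex_gates = list(),
                         limits, duplex_limits = NULL, mu_corr = NULL,
                         prep = NULL, sample_id = "sample") {
  design <- assays$screening
  if (is.null(mu_corr)) {
    mu_corr <- stats::setNames(limits$mu_corr[limits$n_replicates_assayed == 1L],
                               limits$group[limits$n_replicates_assayed == 1L])
  }

  # -- controls ------------------------------------------------------------
  neg_cc <- correct_dup_overlap(classify_droplets(controls$negative, gates))
  pos_cc <- correct_dup_overlap(classify_droplets(controls$positive, gates))
  groups <- .mutant_groups(design)
  lims1 <- limits[limits$n_replicates_assayed == 1L, , drop = FALSE]
  lob <- stats::setNames(lims1$lob95_droplets, lims1$group)
  lod <- stats::setNames(lims1$lod95_droplets, lims1$group)
  controls_ok <- all(neg_cc$counts[groups] <= lob[groups]) &&
    all(pos_cc$counts[groups] >= lod[groups])
  if (!controls_ok) {
    return(structure(list(sample_id = sample_id, controls_ok = FALSE,
                          status = "invalid-controls",
                          screen = NULL, identified = NULL),
                     class = "sample_call"))
  }

  # -- step 1: screening ---------------------------------------------------
  rep_counts <- lapply(screen_chambers, function(ds) {
    correct_dup_overlap(classify_droplets(ds, gates))
  })
  screen_rows <- list()
  calls <- list()
  for (g in groups) {
    counts_g <- vapply(rep_counts, function(cc) cc$counts[[g]], numeric(1))
    calls[[g]] <- call_detection_group(counts_g, c(lob = lob[[g]], lod = lod[[g]]),
                                       group = g)
    screen_rows[[g]] <- data.frame(group = g,
                                   replicate_counts = paste(counts_g, collapse = ";"),
                                   status = calls[[g]]$status,
                                   recommendation = calls[[g]]$recommendation,
                                   stringsAsFactors = FALSE)
  }
  screen_df <- do.call(rbind, screen_rows)
  rownames(screen_df) <- NULL
  pooled <- pool_replicates(rep_counts)
  r <- length(rep_counts)
  screen_quant <- quantify_chamber(pooled, mu_corr = r * mu_corr,
                                   design = design, prep = prep)
  screen_df$maf_pct <- screen_quant$maf_pct[match(screen_df$group, screen_quant$target)]

  positives <- names(Filter(function(cl) cl$status == "positive", calls))
  if (!length(positives)) {
    return(structure(list(sample_id = sample_id, controls_ok = TRUE,
                          status = "negative", screen = screen_df,
                          identified = data.frame()),
                     class = "sample_call"))
  }

  # -- step 2: duplex identification --------------------------------------
  id_rows <- list()
  incomplete <- FALSE
  for (g in positives) {
    cand <- design$groups[[g]]$duplexes
    cand_avail <- intersect(cand, names(duplex_chambers))
    if (!length(cand_avail)) {
      incomplete <- TRUE
      next
    }
    for (dx in cand_avail) {
      ddesign <- assays$duplexes[[dx]]
      dgates <- duplex_gates[[dx]]
      if (is.null(dgates)) .stopf("no gate set supplied for duplex '%s'", dx)
      dcc <- lapply(duplex_chambers[[dx]], classify_droplets, gates = dgates)
      mut_counts <- vapply(dcc, function(cc) cc$counts[[dx]], numeric(1))
      dl <- .duplex_limits_for(dx, duplex_limits, ddesign)
      dcall <- call_detection_group(mut_counts, dl, group = dx)
      if (dcall$status != "positive") next
      dpooled <- pool_replicates(dcc)
      k_corr <- lob_correct_counts(dpooled$counts[[dx]], dx,
                                   stats::setNames(length(dcc) * dl[["mu_corr"]], dx))
      q_mut <- concentration_from_counts(dpooled, dx, mode = "naive", k = k_corr)
      q_wt <- concentration_from_counts(dpooled, "WT", mode = "naive")
      id_rows[[dx]] <- data.frame(
        mutation = dx, group = g,
        copies_per_pcr = q_mut$copies_per_pcr,
        copies_per_ml = if (!is.null(prep)) copies_per_ml_plasma(q_mut, prep) else NA_real_,
        maf_pct = compute_maf(q_mut$copies_per_pcr, q_wt$copies_per_pcr),
        stringsAsFactors = FALSE)
    }
  }
  identified <- if (length(id_rows)) do.call(rbind, id_rows) else data.frame()
  rownames(identified) <- NULL
  status <- if (incomplete && nrow(identified) == 0) "incomplete"
    else if (nrow(identified) == 0) "unconfirmed"
    else if (incomplete) "incomplete"
    else "ok"
  structure(list(sample_id = sample_id, controls_ok = TRUE, status = status,
                 screen = screen_df, identified = identified),
            class = "sample_call")
}

# Resolve lob/lod/mu_corr for a duplex from user-supplied limits or the
# design's calibrated false-positive defaults.
.duplex_limits_for <- function(dx, duplex_limits, ddesign) {
  if (!is.null(duplex_limits)) {
    if (is.data.frame(duplex_limits)) {
      row <- duplex_limits[duplex_limits$group == dx, , drop = FALSE]
      if (nrow(row)) {
        return(c(lob = row$lob95_droplets[1], lod = row$lod95_droplets[1],
                 mu_corr = row$mu_corr[1]))
      }
    } else if (dx %in% names(duplex_limits)) {
      return(duplex_limits[[dx]])
    }
  }
  fp <- ddesign$fp_rate[[dx]] %||% 0.5
  # analytic panel at the design's expected false-positive rate
  mu_corr <- fp + 1.645 * sqrt(fp) / sqrt(34)
  lob <- lob95(mu_corr)
  c(lob = lob, lod = lod95_theoretical(lob)$lod95_droplets, mu_corr = mu_corr)
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("<sample_call '%s': %s (controls %s)>\n", x$sample_id, x$status,
              if (isTRUE(x$controls_ok)) "ok" else "FAILED"))
  if (!is.null(x$screen)) {
    print(x$screen[, c("group", "replicate_counts", "status")])
  }
  if (!is.null(x$identified) && nrow(x$identified)) {
    cat("identified:\n")
    print(x$identified)
  }
  invisible(x)
}
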