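#' Configure a simulated dPCR chamber
#'
#' Describes one digital PCR reaction partitioned into droplets. Defaults
#' follow the platform's operating figures: a 25 uL reaction split into
#' ~0.68 nL droplets, with chambers holding 12,900-25,800 partitions (the
#' default of 20,000 sits mid-range). Only `n_partitions * droplet_volume`
#' of the reaction is analysed; molecules are placed by independent Poisson
#' occupancy with per-droplet mean `copies / reaction_volume * droplet_volume`
#' (volumes in consistent units), so the dead-volume fraction is respected.
#'
#' @param templates Named numeric vector of template copies per reaction.
#'   Names are variant ids of the assay design, plus `WT` for wild-type
#'   fragments of the drop-off amplicon.
#' @param n_partitions Number of droplets formed.
#' @param droplet_volume Droplet volume in nL.
#' @param reaction_volume Reaction volume in uL.
#' @param fp_rate Named numeric vector: mean false-positive droplets per
#'   chamber for each detection group. `NULL` uses the design's calibrated
#'   defaults.
#' @param rain_fraction Probability that a positive channel signal is
#'   attenuated into "rain" (amplitude scaled by a factor uniform in
#'   (0.2, 0.8)).
#' @param noise_sd Gaussian intensity noise SD per channel (arbitrary
#'   fluorescence units).
#' @param baseline,amplitude Negative-cluster level and positive-cluster
#'   amplitude in the same units.
#' @param seed Integer seed; chambers are seeded from `(seed, chamber_id)`
#'   so series are reproducible element-wise. `NULL` uses the current RNG
#'   stream.
#' @param chamber_id Chamber identifier.
#' @return A list of class `chamber_config`.
#' @examples
#' cfg <- chamber_config(templates = c(WT = 1000), seed = 1)
#' @export
chamber_config <- function(templates = c(WT = 0),
                           n_partitions = 20000L,
                           droplet_volume = 0.68,
                           reaction_volume = 25,
                           fp_rate = NULL,
                           rain_fraction = 0.01,
                           noise_sd = 100,
                           baseline = 150,
                           amplitude = 3000,
                           seed = NULL,
                           chamber_id = "chamber1") {
  if (is.null(names(templates)) || any(!nzchar(names(templates)))) {
    .stopf("templates must be a named vector (variant ids and/or 'WT')")
  }
  if (any(templates < 0)) .stopf("template copy numbers must be >= 0")
  if (n_partitions < 0) .stopf("n_partitions must be >= 0")
  if (droplet_volume <= 0 || reaction_volume <= 0) {
    .stopf("droplet_volume and reaction_volume must be positive")
  }
  if (rain_fraction < 0 || rain_fraction > 1) .stopf("rain_fraction must be in [0, 1]")
  structure(list(templates = templates, n_partitions = as.integer(n_partitions),
                 droplet_volume = droplet_volume, reaction_volume = reaction_volume,
                 fp_rate = fp_rate, rain_fraction = rain_fraction,
                 noise_sd = noise_sd, baseline = baseline, amplitude = amplitude,
                 seed = seed, chamber_id = chamber_id),
            class = "chamber_config")
}

# Per-droplet Poisson mean for a template at `copies` copies/reaction.
.lambda_per_droplet <- function(copies, cfg) {
  copies / (cfg$reaction_volume * 1000) * cfg$droplet_volume
}

#' Simulate one droplet chamber
#'
#' Places template molecules into droplets by independent Poisson
#' occupancy, fires the design's probes on each droplet's content
#' (drop-off probes bind intact-hotspot templates, reference probes bind
#' any template of their amplicon, mutation-specific probes bind their
#' variants), attenuates a `rain_fraction` of positive signals, injects
#' group-specific false-positive droplets by corrupting empty droplets
#' (partition count is conserved), and adds Gaussian intensity noise.
#'
#' Co-occupancy is modeled faithfully: a droplet holding both a wild-type
#' and a hotspot-mutant template lights the drop-off probe and is
#' indistinguishable from wild-type-only -- the masking that the
#' conditional estimator in [concentration_from_counts()] corrects for.
#' Templates that no probe of the design binds are carried but produce no
#' signal (a mutation outside a duplex's target, for instance).
#'
#' @param cfg A [chamber_config()].
#' @param design An `assay_design` (see [build_erbb2_assays()]).
#' @return A data frame of class `droplet_set` with columns `chamber_id`,
#'   `droplet_id`, `FAM`, `HEX`, `Cy5`, carrying the chamber geometry and a
#'   per-droplet provenance table (true signature, decoded true class,
#'   false-positive flag) as attributes.
#' @examples
#' design <- build_erbb2_assays()$screening
#' ds <- simulate_chamber(chamber_config(c(WT = 1000), seed = 7), design)
#' head(ds)
#' @export
simulate_chamber <- function(cfg, design) {
  stopifnot(inherits(cfg, "chamber_config"))
  validate_assay_design(design)
  # templates with no probe in this design are carried but invisible --
  # e.g. a second mutation in the sample when running a single duplex
  if (cfg$n_partitions == 0L && sum(cfg$templates) > 0) {
    .stopf("expected occupancy > 0 with zero partitions")
  }
  body <- function() .simulate_chamber_impl(cfg, design)
  if (!is.null(cfg$seed)) {
    withr::with_seed(.chamber_seed(cfg$seed, cfg$chamber_id), body())
  } else {
    body()
  }
}

.simulate_chamber_impl <- function(cfg, design) {
  n <- cfg$n_partitions
  tpl <- cfg$templates[cfg$templates > 0]
  occ <- matrix(FALSE, nrow = n, ncol = length(tpl),
                dimnames = list(NULL, names(tpl)))
  for (t in names(tpl)) {
    occ[, t] <- stats::rpois(n, .lambda_per_droplet(tpl[[t]], cfg)) > 0L
  }
  channels <- c("FAM", "HEX", "Cy5")
  lvl <- matrix(0, nrow = n, ncol = 3L, dimnames = list(NULL, channels))
  for (p in design$probes$name) {
    ch <- design$probes$channel[design$probes$name == p]
    b <- design$binds[[p]]
    for (t in intersect(names(b), colnames(occ))) {
      lvl[, ch] <- pmax(lvl[, ch], b[[t]] * occ[, t])
    }
  }
  true_sig <- paste0(as.integer(lvl[, 1] > 0), as.integer(lvl[, 2] > 0),
                     as.integer(lvl[, 3] > 0))
  true_class <- unname(design$decode[true_sig])

  # group-specific false positives: corrupt empty droplets in place,
  # placing them at the group's canonical cluster position
  fp_rate <- cfg$fp_rate %||% design$fp_rate
  fp_group <- rep(NA_character_, n)
  for (g in intersect(names(fp_rate), .mutant_groups(design))) {
    n_fp <- stats::rpois(1L, fp_rate[[g]])
    if (n_fp == 0L) next
    empties <- which(rowSums(lvl) == 0 & is.na(fp_group))
    take <- if (length(empties) <= n_fp) empties else sample(empties, n_fp)
    if (!length(take)) next
    fp_lvl <- .canonical_levels(design, design$groups[[g]]$members[1])
    lvl[take, ] <- matrix(fp_lvl, nrow = length(take), ncol = 3L, byrow = TRUE)
    fp_group[take] <- g
  }

  # rain: attenuate a fraction of positive signals
  rained <- rep(FALSE, n)
  if (cfg$rain_fraction > 0) {
    pos <- which(lvl > 0)
    is_rain <- stats::runif(length(pos)) < cfg$rain_fraction
    lvl[pos[is_rain]] <- lvl[pos[is_rain]] *
      stats::runif(sum(is_rain), 0.2, 0.8)
    rained[((pos[is_rain] - 1L) %% n) + 1L] <- TRUE
  }

  intens <- cfg$baseline + cfg$amplitude * lvl +
    matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), nrow = n)
  ds <- data.frame(chamber_id = cfg$chamber_id,
                   droplet_id = seq_len(n),
                   FAM = intens[, 1], HEX = intens[, 2], Cy5 = intens[, 3],
                   stringsAsFactors = FALSE)
  class(ds) <- c("droplet_set", "data.frame")
  attr(ds, "n_partitions") <- n
  attr(ds, "droplet_volume") <- cfg$droplet_volume
  attr(ds, "reaction_volume") <- cfg$reaction_volume
  attr(ds, "design") <- design$name
  attr(ds, "signal") <- list(baseline = cfg$baseline, amplitude = cfg$amplitude,
                             noise_sd = cfg$noise_sd)
  attr(ds, "provenance") <- data.frame(true_signature = true_sig,
                                       true_class = true_class,
                                       fp_group = fp_group,
                                       rained = rained,
                                       stringsAsFactors = FALSE)
  attr(ds, "occupancy") <- occ
  ds
}

#' Simulate a serial-dilution MAF series
#'
#' Emulates the sensitivity-validation design: mutant control fragments
#' serially diluted in a constant wild-type background of 10,000
#' copies/PCR. For a theoretical MAF of `m` percent the mutant input is
#' `round(m / 100 * background)` copies/PCR. Dilutions are assayed in
#' triplicate by default, with a fourth replicate at MAF 0.05%.
#'
#' @param base A [chamber_config()] used as the template for every chamber
#'   (its `templates` field is replaced).
#' @param design An `assay_design`.
#' @param mafs Theoretical MAFs in percent, positive and descending.
#' @param replicates Replicates per dilution (the 0.05% level always gets
#'   at least 4).
#' @param variant Variant id carrying the mutant copies.
#' @param background Wild-type copies/PCR.
#' @return A list of `droplet_set` objects; each carries attributes
#'   `maf_theoretical`, `replicate` and `mutant_copies`.
#' @export
simulate_dilution_series <- function(base, design,
                                     mafs = c(5, 2.5, 1, 0.5, 0.25, 0.1, 0.05),
                                     replicates = 3L,
                                     variant = "V777L_GtoT",
                                     background = 10000) {
  stopifnot(inherits(base, "chamber_config"))
  if (any(mafs <= 0)) .stopf("mafs must be positive percentages")
  if (is.unsorted(rev(mafs), strictly = FALSE)) .stopf("mafs must be descending")
  out <- list()
  for (m in mafs) {
    n_rep <- if (isTRUE(all.equal(m, 0.05))) max(replicates, 4L) else replicates
    mut_copies <- round(m / 100 * background)
    for (r in seq_len(n_rep)) {
      cfg <- base
      cfg$templates <- stats::setNames(c(background, mut_copies), c("WT", variant))
      cfg$chamber_id <- sprintf("dil_maf%g_rep%d", m, r)
      ds <- simulate_chamber(cfg, design)
      attr(ds, "maf_theoretical") <- m
      attr(ds, "replicate") <- r
      attr(ds, "mutant_copies") <- mut_copies
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}

#' Simulate a blank (wild-type-only) panel
#'
#' Generates `n` chambers containing only wild-type template (default
#' 10,000 copies/PCR, the panel design used for limit-of-blank
#' calibration, with 34 replicates) and tallies the decoded false-positive
#' droplets per mutant detection group in each chamber.
#'
#' @param cfg A [chamber_config()]; its `templates` should contain only
#'   `WT` (defaulting to 10,000 copies/PCR if unset).
#' @param design An `assay_design`.
#' @param n Number of replicate chambers (>= 2).
#' @return An object of class `blank_panel`: a replicate-by-group integer
#'   matrix of false-positive droplet counts with attributes
#'   `n_replicates` and `background_copies`.
#' @export
simulate_blank_panel <- function(cfg, design, n = 34L) {
  stopifnot(inherits(cfg, "chamber_config"))
  if (n < 2L) .stopf("a blank panel needs at least 2 replicates")
  if (any(names(cfg$templates) != "WT" & cfg$templates > 0)) {
    .stopf("blank panels must contain wild-type template only")
  }
  if (!"WT" %in% names(cfg$templates) || cfg$templates[["WT"]] == 0) {
    cfg$templates <- c(WT = 10000)
  }
  groups <- .mutant_groups(design)
  counts <- matrix(0L, nrow = n, ncol = length(groups),
                   dimnames = list(NULL, groups))
  for (i in seq_len(n)) {
    ci <- cfg
    ci$chamber_id <- sprintf("blank%03d", i)
    ds <- simulate_chamber(ci, design)
    counts[i, ] <- .threshold_gate_counts(ds, design)[groups]
  }
  structure(counts, class = c("blank_panel", class(counts)),
            n_replicates = n, background_copies = cfg$templates[["WT"]])
}

# Count droplets per gate using the simulator's known signal levels.
# Mirrors the polygon-gate bands: positive above 45% of the amplitude,
# negative below 15%, mid-band ("m", the attenuated duplication clusters)
# between 30% and 90%, and the intermediate rain band satisfies neither
# "+" nor "-". Used for blank panels and as a fast internal check; polygon
# gating is the user-facing route.
.threshold_gate_counts <- function(ds, design) {
  sig <- attr(ds, "signal")
  hi <- sig$baseline + 0.45 * sig$amplitude
  lo <- sig$baseline + 0.15 * sig$amplitude
  m_lo <- sig$baseline + 0.30 * sig$amplitude
  m_hi <- sig$baseline + 0.90 * sig$amplitude
  ch_mat <- cbind(FAM = ds$FAM, HEX = ds$HEX, Cy5 = ds$Cy5)
  out <- stats::setNames(integer(length(design$gate_defs)),
                         vapply(design$gate_defs, `[[`, character(1), "name"))
  for (g in design$gate_defs) {
    keep <- rep(TRUE, nrow(ds))
    for (i in seq_along(g$plane)) {
      v <- ch_mat[, g$plane[i]]
      keep <- keep & switch(g$axis_state[i],
                            "+" = v > hi,
                            "-" = v < lo,
                            "m" = v > m_lo & v < m_hi,
                            "*" = TRUE)
    }
    out[g$name] <- sum(keep)
  }
  out
}

#' Simulate a patient cohort results table
#'
#' Generates a plasma-screening cohort with the marginal structure of the
#' study population: histology strata (IBC-NST, pure ILC, mixed ILC) with
#' stratum-specific mutation prevalence, one or occasionally two mutations
#' per positive patient, per-mutation plasma concentrations (log-uniform
#' copies/mL) and MAFs, plasma cfDNA concentrations, and a matched-tissue
#' result for a subset of positive patients.
#'
#' Defaults emulate the published cohort: 272 patients split 189/51/32
#' across IBC-NST / pure ILC / mixed ILC with stratum prevalences 5/189,
#' 3/51 and 1/32 (3.3% overall), a third of positives carrying two
#' mutations, and a mutation spectrum proportional to the reported
#' 12-event frequency table.
#'
#' @param n_patients Number of patients.
#' @param histology_weights Named weights for the three histology strata.
#' @param prevalence Named per-stratum probability that a patient carries
#'   at least one detectable mutation.
#' @param double_fraction Probability that a positive patient carries two
#'   mutations.
#' @param spectrum Named sampling weights over protein-level mutation
#'   names.
#' @param copies_log10_range Range of `log10(copies/mL)` for mutation
#'   calls.
#' @param maf_log10_range Range of `log10(MAF %)` for mutation calls.
#' @param cfdna_meanlog,cfdna_sdlog Log-normal parameters for plasma cfDNA
#'   (ng/mL); defaults give a median of 14.1 ng/mL.
#' @param plasma_volume_ml Plasma volume per sample.
#' @param tissue_tested_fraction Fraction of positive patients with a
#'   matched tissue result.
#' @param tissue_concordant_fraction Probability that a tested tissue
#'   contains all plasma mutations.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A data frame of class `cohort_table`; one row per
#'   patient/sample/mutation (mutation `NA` for negative patients). See
#'   [cohort_summary()] for the downstream analysis.
#' @export
simulate_cohort_table <- function(n_patients = 272L,
                                  histology_weights = c("IBC-NST" = 189, "pure ILC" = 51, "mixed ILC" = 32),
                                  prevalence = c("IBC-NST" = 5 / 189, "pure ILC" = 3 / 51, "mixed ILC" = 1 / 32),
                                  double_fraction = 1 / 3,
                                  spectrum = c(L755S = 3, V777L = 3, S310Y = 2, L869R = 2, S310F = 1, D769H = 1),
                                  copies_log10_range = c(1, 3.9),
                                  maf_log10_range = c(-1.25, 1.5),
                                  cfdna_meanlog = log(14.1),
                                  cfdna_sdlog = 1.25,
                                  plasma_volume_ml = 4,
                                  tissue_tested_fraction = 6 / 9,
                                  tissue_concordant_fraction = 5 / 6,
                                  seed = NULL) {
  if (any(prevalence < 0 | prevalence > 1)) .stopf("prevalence must be in [0, 1]")
  body <- function() {
    histology <- sample(names(histology_weights), n_patients, replace = TRUE,
                        prob = histology_weights / sum(histology_weights))
    rows <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%03d", i)
      cf <- stats::rlnorm(1, cfdna_meanlog, cfdna_sdlog)
      pos <- stats::runif(1) < prevalence[[histology[i]]]
      if (!pos) {
        rows[[i]] <- data.frame(patient_id = pid, sample_index = 1L,
                                histology = histology[i],
                                plasma_volume_ml = plasma_volume_ml,
                                cfdna_ng_per_ml = cf, mutation = NA_character_,
                                copies_per_ml = NA_real_, maf_pct = NA_real_,
                                tissue_tested = FALSE,
                                tissue_mutations = NA_character_,
                                stringsAsFactors = FALSE)
        next
      }
      n_mut <- 1L + (stats::runif(1) < double_fraction)
      muts <- sample(names(spectrum), n_mut, prob = spectrum / sum(spectrum))
      copies <- 10^stats::runif(n_mut, copies_log10_range[1], copies_log10_range[2])
      mafs <- pmin(100, 10^stats::runif(n_mut, maf_log10_range[1], maf_log10_range[2]))
      tested <- stats::runif(1) < tissue_tested_fraction
      tissue <- if (!tested) NA_character_ else if (stats::runif(1) < tissue_concordant_fraction) {
        paste(muts, collapse = ";")
      } else ""
      rows[[i]] <- data.frame(patient_id = pid, sample_index = 1L,
                              histology = histology[i],
                              plasma_volume_ml = plasma_volume_ml,
                              cfdna_ng_per_ml = cf, mutation = muts,
                              copies_per_ml = copies, maf_pct = mafs,
                              tissue_tested = tested,
                              tissue_mutations = tissue,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cohort_table", "data.frame")
    out
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), body()) else body()
}

#' Write / read droplet tables as CSV
#'
#' Droplet tables are exchanged as plain CSV with columns `chamber_id`,
#' `droplet_id`, `FAM`, `HEX`, `Cy5`; chamber geometry travels in a
#' side-car header comment line.
#'
#' @param ds A `droplet_set`.
#' @param path Output path.
#' @return `write_droplets()` returns `path` invisibly; `read_droplets()`
#'   returns a `droplet_set`.
#' @export
write_droplets <- function(ds, path) {
  stopifnot(inherits(ds, "droplet_set"))
  hdr <- sprintf("# n_partitions=%d droplet_volume=%g reaction_volume=%g design=%s",
                 attr(ds, "n_partitions"), attr(ds, "droplet_volume"),
                 attr(ds, "reaction_volume"), attr(ds, "design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(ds)[, c("chamber_id", "droplet_id", "FAM", "HEX", "Cy5")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_droplets
#' @export
read_droplets <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- list(n_partitions = NA, droplet_volume = 0.68, reaction_volume = 25,
               design = NA_character_)
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=")[[1]]
      if (length(parts) == 2L) meta[[parts[1]]] <- utils::type.convert(parts[2], as.is = TRUE)
    }
  }
  ds <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(ds) <- c("droplet_set", "data.frame")
  attr(ds, "n_partitions") <- if (is.na(meta$n_partitions)) nrow(ds) else as.integer(meta$n_partitions)
  attr(ds, "droplet_volume") <- meta$droplet_volume
  attr(ds, "reaction_volume") <- meta$reaction_volume
  attr(ds, "design") <- meta$design
  ds
}
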