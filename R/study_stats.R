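#' Coefficient of variation in percent
#'
#' `CV% = 100 * sigma / mu` with the sample SD.
#'
#' @param values Numeric vector of >= 2 replicate results with non-zero
#'   mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(9, 10, 11))  # 10
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) .stopf("CV needs >= 2 replicate values")
  mu <- mean(values)
  if (mu == 0) .stopf("CV undefined for zero mean")
  100 * stats::sd(values) / mu
}

#' Coefficient of determination of a calibration line
#'
#' Ordinary least-squares R-squared of measured against expected
#' concentrations.
#'
#' @param expected,measured Numeric vectors (>= 3 points; `expected` must
#'   vary).
#' @return R-squared in `[0, 1]`.
#' @export
linearity_r2 <- function(expected, measured) {
  if (length(expected) != length(measured)) .stopf("length mismatch")
  if (length(expected) < 3L) .stopf("linearity needs >= 3 points")
  if (stats::sd(expected) == 0) .stopf("expected values are constant; R2 undefined")
  fit <- stats::lm(measured ~ expected)
  summary(fit)$r.squared
}

#' Sensitivity from a serial-dilution study
#'
#' Applies the positivity rule down the dilution ladder: for each
#' detection group the lowest theoretical MAF at which at least two
#' replicates reach the LOD95 in raw positive droplets is the detection
#' floor, and the sensitivity value is the mean measured MAF across that
#' dilution's replicates.
#'
#' @param series Data frame with one row per chamber: columns `group`,
#'   `maf_theoretical`, `replicate`, `positive_droplets` (raw count) and
#'   `maf_measured`.
#' @param limits A `limit_estimates` table (single-replicate rows used).
#' @return A data frame of class `dilution_study_result`, one row per
#'   group: `group`, `lowest_positive_maf` (NA when never positive),
#'   `sensitivity_maf_pct`, `detected`.
#' @export
sensitivity_from_dilutions <- function(series, limits) {
  need <- c("group", "maf_theoretical", "replicate", "positive_droplets", "maf_measured")
  if (!all(need %in% names(series))) {
    .stopf("series needs columns: %s", paste(need, collapse = ", "))
  }
  lims1 <- limits[limits$n_replicates_assayed == 1L, , drop = FALSE]
  rows <- lapply(unique(series$group), function(g) {
    lod <- lims1$lod95_droplets[lims1$group == g]
    if (!length(lod)) .stopf("no limits for group '%s'", g)
    sub <- series[series$group == g, , drop = FALSE]
    mafs <- sort(unique(sub$maf_theoretical))
    lowest <- NA_real_
    sens <- NA_real_
    for (m in mafs) {
      lvl <- sub[sub$maf_theoretical == m, , drop = FALSE]
      if (sum(lvl$positive_droplets >= lod) >= 2L) {
        lowest <- m
        sens <- mean(lvl$maf_measured)
        break
      }
    }
    data.frame(group = g, lowest_positive_maf = lowest,
               sensitivity_maf_pct = sens, detected = !is.na(lowest),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dilution_study_result", "data.frame")
  out
}

#' Summarise a plasma-screening cohort
#'
#' Computes the headline cohort statistics from a long-format cohort
#' table (one row per patient/sample/mutation, mutation `NA` for negative
#' samples): patient-level mutation prevalence overall and by histology
#' stratum (IBC-NST, pure ILC, and pure plus mixed ILC combined), the
#' mutation-event frequency spectrum (a patient with two mutations counts
#' once in prevalence but contributes two events), per-mutation
#' distributions of copies/mL and MAF, plasma-vs-tissue concordance (a
#' matched pair is concordant when every plasma mutation of the patient is
#' found in tissue), and the median plasma cfDNA concentration.
#'
#' Printed percentages use round-half-away-from-zero at the conventional
#' precisions (one decimal for prevalence, two for the spectrum, whole
#' percent for concordance).
#'
#' @param table A `cohort_table` data frame (see
#'   [simulate_cohort_table()] or [example_cohort_table()] for the
#'   schema).
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(table) {
  need <- c("patient_id", "sample_index", "histology", "cfdna_ng_per_ml",
            "mutation", "copies_per_ml", "maf_pct", "tissue_tested",
            "tissue_mutations")
  if (!all(need %in% names(table))) {
    .stopf("cohort table needs columns: %s", paste(need, collapse = ", "))
  }
  key <- paste(table$patient_id, table$sample_index, table$mutation)
  if (any(duplicated(key[!is.na(table$mutation)]))) {
    .stopf("duplicate (patient, sample, mutation) rows")
  }
  if (any(stats::na.omit(table$maf_pct) < 0 | stats::na.omit(table$maf_pct) > 100)) {
    .stopf("MAF values must lie in [0, 100]")
  }

  patients <- unique(table$patient_id)
  n_patients <- length(patients)
  pos_tab <- table[!is.na(table$mutation), , drop = FALSE]
  pos_patients <- unique(pos_tab$patient_id)
  n_positive <- length(pos_patients)

  hist_of <- tapply(table$histology, table$patient_id, function(h) h[1])
  strata <- list("IBC-NST" = names(hist_of)[hist_of == "IBC-NST"],
                 "pure ILC" = names(hist_of)[hist_of == "pure ILC"],
                 "pure+mixed ILC" = names(hist_of)[hist_of %in% c("pure ILC", "mixed ILC")])
  prev_by_hist <- vapply(strata, function(ids) {
    if (!length(ids)) return(NA_real_)
    round_half_away(100 * sum(ids %in% pos_patients) / length(ids), 1)
  }, numeric(1))

  # mutation events: one per (patient, mutation)
  ev <- unique(pos_tab[, c("patient_id", "mutation")])
  events <- table(ev$mutation)
  n_events <- sum(events)
  rel_freq <- round_half_away(100 * as.numeric(events) / n_events, 2)
  names(rel_freq) <- names(events)
  spectrum <- data.frame(mutation = names(events),
                         n = as.integer(events),
                         relative_frequency_pct = rel_freq,
                         stringsAsFactors = FALSE)
  spectrum <- spectrum[order(-spectrum$n, spectrum$mutation), ]
  rownames(spectrum) <- NULL

  per_mut <- do.call(rbind, lapply(names(events), function(m) {
    sub <- pos_tab[pos_tab$mutation == m, , drop = FALSE]
    data.frame(mutation = m,
               copies_median = stats::median(sub$copies_per_ml),
               copies_min = min(sub$copies_per_ml),
               copies_max = max(sub$copies_per_ml),
               maf_median = stats::median(sub$maf_pct),
               maf_min = min(sub$maf_pct), maf_max = max(sub$maf_pct),
               stringsAsFactors = FALSE)
  }))

  tested <- unique(table$patient_id[table$tissue_tested %in% TRUE])
  tested <- intersect(tested, pos_patients)
  n_agree <- 0L
  for (p in tested) {
    plasma_muts <- unique(pos_tab$mutation[pos_tab$patient_id == p])
    tmut <- table$tissue_mutations[table$patient_id == p]
    tmut <- tmut[!is.na(tmut)][1]
    tissue_muts <- if (is.na(tmut) || !nzchar(tmut)) character(0) else
      strsplit(tmut, ";")[[1]]
    if (all(plasma_muts %in% tissue_muts)) n_agree <- n_agree + 1L
  }
  concord_pct <- if (length(tested)) {
    round_half_away(100 * n_agree / length(tested), 0)
  } else NA_real_

  samples <- unique(table[, c("patient_id", "sample_index", "cfdna_ng_per_ml")])
  structure(list(
    n_patients = n_patients,
    n_samples = nrow(samples),
    n_positive_patients = n_positive,
    prevalence_pct = round_half_away(100 * n_positive / n_patients, 1),
    prevalence_by_histology_pct = prev_by_hist,
    n_mutation_events = as.integer(n_events),
    spectrum = spectrum,
    per_mutation = per_mut,
    concordance = list(n_agree = n_agree, n_tested = length(tested),
                       pct = concord_pct),
    median_cfdna_ng_per_ml = stats::median(samples$cfdna_ng_per_ml)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d samples); %d positive (%.1f%%)\n",
              x$n_patients, x$n_samples, x$n_positive_patients, x$prevalence_pct))
  cat("Prevalence by histology (%):\n")
  print(x$prevalence_by_histology_pct)
  cat(sprintf("%d mutation events:\n", x$n_mutation_events))
  print(x$spectrum)
  if (x$concordance$n_tested > 0) {
    cat(sprintf("Plasma/tissue concordance: %d/%d (%g%%)\n",
                x$concordance$n_agree, x$concordance$n_tested, x$concordance$pct))
  }
  cat(sprintf("Median cfDNA: %.1f ng/mL\n", x$median_cfdna_ng_per_ml))
  invisible(x)
}

#' Read / write cohort tables as CSV
#'
#' @param table A `cohort_table`.
#' @param path File path.
#' @return `write_cohort_table()` returns `path` invisibly;
#'   `read_cohort_table()` returns a `cohort_table`.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
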