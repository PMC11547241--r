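#' Describe sample preparation volumes
#'
#' Records the volume chain from plasma to PCR: cfDNA is extracted from
#' `plasma_volume` mL of plasma into `eluate_volume` uL, of which
#' `input_volume` uL enter the `reaction_volume` uL PCR, possibly after
#' dilution. Used by [copies_per_ml_plasma()].
#'
#' @param plasma_volume Plasma volume in mL (> 0).
#' @param eluate_volume Elution volume in uL (default 50).
#' @param input_volume cfDNA input per PCR in uL (default 15).
#' @param reaction_volume PCR volume in uL (default 25).
#' @param dilution_factor Pre-PCR dilution factor (>= 1).
#' @return A list of class `sample_prep`.
#' @export
sample_prep <- function(plasma_volume, eluate_volume = 50,
                        input_volume = 15, reaction_volume = 25,
                        dilution_factor = 1) {
  if (plasma_volume <= 0) .stopf("plasma volume must be positive")
  if (any(c(eluate_volume, input_volume, reaction_volume) <= 0)) {
    .stopf("all volumes must be positive")
  }
  if (dilution_factor < 1) .stopf("dilution_factor must be >= 1")
  if (input_volume > eluate_volume * dilution_factor) {
    .stopf("input volume exceeds available (diluted) eluate")
  }
  structure(list(plasma_volume = plasma_volume, eluate_volume = eluate_volume,
                 input_volume = input_volume, reaction_volume = reaction_volume,
                 dilution_factor = dilution_factor),
            class = "sample_prep")
}

#' Poisson concentration estimate from cluster counts
#'
#' Converts a positive-droplet count `k` out of `N` partitions into a mean
#' per-droplet occupancy and copies per reaction. Two estimators are
#' available:
#' \describe{
#'   \item{naive}{`lambda = -log(1 - k/N)`, the standard dPCR estimator.
#'     For a drop-off mutant target this underestimates the mutant load,
#'     because mutant molecules co-encapsulated with a wild-type molecule
#'     are masked inside the wild-type cluster.}
#'   \item{conditional}{For drop-off mutant targets: restrict to the
#'     wild-type-negative subpopulation of `N - k_WT` droplets, within
#'     which mutant occupancy is unbiased (occupancies are independent):
#'     `lambda_mut = -log((N - k_WT - k) / (N - k_WT))`.}
#' }
#' Copies per reaction refer to the full reaction volume (dead volume
#' included): `copies = lambda / droplet_volume * reaction_volume`. The
#' analysed fraction `N * droplet_volume / reaction_volume` is reported
#' alongside.
#'
#' The 95% CI is a normal interval on `lambda` from the binomial variance
#' of `k` propagated through the log transform
#' (`var(lambda) = k / (N (N - k))`); `ci = "clopper-pearson"` gives the
#' exact interval on the positive fraction, transformed.
#'
#' @param counts A `cluster_counts` object (see [classify_droplets()]),
#'   dup-corrected where relevant.
#' @param target Detection-class (gate) name to quantify.
#' @param mode `"naive"` or `"conditional"`.
#' @param k Optional override for the positive-droplet count (e.g. a
#'   LOB-corrected, hence possibly non-integer, count).
#' @param wt Name of the wild-type gate (conditional mode).
#' @param ci CI method.
#' @return A one-row data frame of class `quant_result`: `target`,
#'   `k`, `n_effective`, `lambda_per_droplet`, `copies_per_pcr`,
#'   `ci_low`, `ci_high` (copies/PCR scale), `analyzed_fraction`.
#' @examples
#' # k = 1000 of N = 20000 at 0.68 nL / 25 uL -> lambda 0.0513, ~1886 copies/PCR
#' @export
concentration_from_counts <- function(counts, target,
                                      mode = c("naive", "conditional"),
                                      k = NULL, wt = "WT",
                                      ci = c("normal", "clopper-pearson")) {
  mode <- match.arg(mode)
  ci <- match.arg(ci)
  stopifnot(inherits(counts, "cluster_counts"))
  if (!target %in% names(counts$counts)) {
    .stopf("target '%s' not among gate counts (%s)", target,
           paste(names(counts$counts), collapse = ", "))
  }
  N <- counts$total_partitions
  k <- if (is.null(k)) counts$counts[[target]] else k
  n_eff <- N
  if (mode == "conditional") {
    if (!wt %in% names(counts$counts)) {
      .stopf("conditional mode needs a '%s' gate count", wt)
    }
    n_eff <- N - counts$counts[[wt]]
  }
  if (k > n_eff) .stopf("positive droplets (%g) exceed partitions (%g): data integrity error", k, n_eff)
  if (k == n_eff && k > 0) {
    .stopf("all %g partitions positive for '%s': saturated chamber, dilute the sample", n_eff, target)
  }
  v <- counts$droplet_volume %||% 0.68
  V <- counts$reaction_volume %||% 25
  scale <- (V * 1000) / v            # lambda -> copies/reaction
  p <- k / n_eff
  lambda <- -log(1 - p)
  if (ci == "normal") {
    se <- if (k > 0) sqrt(k / (n_eff * (n_eff - k))) else 0
    lo <- max(0, lambda - 1.96 * se)
    hi <- lambda + 1.96 * se
  } else {
    kc <- ceiling(k)  # exact interval needs an integer count
    plo <- if (kc == 0) 0 else stats::qbeta(0.025, kc, n_eff - kc + 1)
    phi <- if (kc == n_eff) 1 else stats::qbeta(0.975, kc + 1, n_eff - kc)
    lo <- -log(1 - plo)
    hi <- -log(1 - phi)
  }
  out <- data.frame(target = target, k = k, n_effective = n_eff,
                    lambda_per_droplet = lambda,
                    copies_per_pcr = lambda * scale,
                    ci_low = lo * scale, ci_high = hi * scale,
                    analyzed_fraction = N * v / (V * 1000),
                    stringsAsFactors = FALSE)
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Limit-of-blank correction of a positive-droplet count
#'
#' Subtracts the corrected blank mean of the detection group (the expected
#' number of false-positive droplets per chamber, see
#' [corrected_blank_mean()]) from the observed count, flooring at zero.
#'
#' @param k Observed positive-droplet count.
#' @param group Detection-group name.
#' @param blanks A `blank_panel` (counts matrix with groups as columns) or
#'   a named numeric vector of corrected blank means per group.
#' @return The corrected (possibly non-integer) count, `>= 0`.
#' @examples
#' lob_correct_counts(10, "776-779_MUT", c("776-779_MUT" = 2.28))  # 7.72
#' @export
lob_correct_counts <- function(k, group, blanks) {
  if (k < 0) .stopf("count must be >= 0")
  mu_corr <- if (inherits(blanks, "blank_panel") || is.matrix(blanks)) {
    if (!group %in% colnames(blanks)) {
      .stopf("blank panel has no counts for group '%s'", group)
    }
    corrected_blank_mean(blanks[, group])
  } else {
    if (!group %in% names(blanks)) {
      .stopf("no corrected blank mean supplied for group '%s'", group)
    }
    blanks[[group]]
  }
  max(0, k - mu_corr)
}

#' Mutant allele frequency
#'
#' `MAF = 100 * mutant / (mutant + wild-type)`, on the copies scale.
#'
#' @param mut_copies,wt_copies Copy numbers (same units), not both zero.
#' @return MAF in percent.
#' @examples
#' compute_maf(5, 9995)  # 0.05
#' @export
compute_maf <- function(mut_copies, wt_copies) {
  if (any(c(mut_copies, wt_copies) < 0)) .stopf("copy numbers must be >= 0")
  if (mut_copies + wt_copies == 0) {
    .stopf("MAF undefined: mutant and wild-type copies are both zero")
  }
  100 * mut_copies / (mut_copies + wt_copies)
}

#' Convert copies per reaction to copies per mL of plasma
#'
#' Scales through the preparation chain: only `input_volume` of the
#' (possibly diluted) `eluate_volume` enters the PCR, and the eluate
#' derives from `plasma_volume` mL of plasma:
#' `copies/mL = copies/PCR * dilution * (eluate / input) / plasma_volume`.
#'
#' @param copies_per_pcr Copies per reaction (numeric, or a `quant_result`
#'   row from [concentration_from_counts()]).
#' @param prep A [sample_prep()].
#' @return Copies per mL of plasma.
#' @examples
#' copies_per_ml_plasma(30, sample_prep(plasma_volume = 4))  # 25
#' @export
copies_per_ml_plasma <- function(copies_per_pcr, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  if (inherits(copies_per_pcr, "quant_result")) {
    copies_per_pcr <- copies_per_pcr$copies_per_pcr
  }
  copies_per_pcr * prep$dilution_factor *
    (prep$eluate_volume / prep$input_volume) / prep$plasma_volume
}

#' Pool replicate chambers
#'
#' Sums gate counts and partitions across replicate chambers of the same
#' assay, increasing sensitivity for low-concentration samples. Chamber
#' identifiers are preserved.
#'
#' @param counts_list List of `cluster_counts` sharing design and gate
#'   names.
#' @return A pooled `cluster_counts`.
#' @export
pool_replicates <- function(counts_list) {
  if (inherits(counts_list, "cluster_counts")) counts_list <- list(counts_list)
  stopifnot(length(counts_list) >= 1L,
            all(vapply(counts_list, inherits, logical(1), "cluster_counts")))
  designs <- unique(vapply(counts_list, `[[`, character(1), "design"))
  if (length(designs) != 1L) {
    .stopf("cannot pool chambers from different assays: %s",
           paste(designs, collapse = ", "))
  }
  gate_names <- names(counts_list[[1]]$counts)
  for (cc in counts_list[-1]) {
    if (!identical(names(cc$counts), gate_names)) {
      .stopf("cannot pool chambers classified with different gate sets")
    }
  }
  if (length(unique(vapply(counts_list, `[[`, logical(1), "dup_corrected"))) != 1L) {
    .stopf("cannot pool a mixture of dup-corrected and raw counts")
  }
  pooled <- counts_list[[1]]
  pooled$chamber_id <- unlist(lapply(counts_list, `[[`, "chamber_id"))
  pooled$total_partitions <- sum(vapply(counts_list, `[[`, numeric(1), "total_partitions"))
  pooled$counts <- Reduce(`+`, lapply(counts_list, `[[`, "counts"))
  pooled$n_classified <- sum(vapply(counts_list, `[[`, numeric(1), "n_classified"))
  pooled$n_empty <- sum(vapply(counts_list, `[[`, numeric(1), "n_empty"))
  pooled$unclassified <- sum(vapply(counts_list, `[[`, numeric(1), "unclassified"))
  pooled$assigned <- NULL
  pooled
}

#' Quantify every mutant detection group of a chamber
#'
#' Convenience wrapper producing the standard results table: for each
#' mutant group the raw count, LOB-corrected count, occupancy, copies per
#' reaction, copies per mL of plasma (when `prep` is given) and MAF
#' against the wild-type gate. The drop-off hotspot group is quantified
#' with the conditional estimator; other groups with the naive one.
#'
#' @param counts A dup-corrected `cluster_counts`.
#' @param mu_corr Named corrected blank means per group (droplets/chamber);
#'   missing groups get no LOB correction.
#' @param design The `assay_design` used.
#' @param prep Optional [sample_prep()].
#' @param conditional_targets Groups quantified conditionally on the
#'   wild-type-negative subpopulation.
#' @return A data frame with one row per mutant group: `target`, `k_raw`,
#'   `k_corrected`, `lambda`, `copies_per_pcr`, `copies_per_ml`,
#'   `maf_pct`, `ci_low`, `ci_high`.
#' @export
quantify_chamber <- function(counts, mu_corr = NULL, design, prep = NULL,
                             conditional_targets = "776-779_MUT") {
  stopifnot(inherits(counts, "cluster_counts"))
  if ("Y772_A775dup-G778_P780dup" %in% names(counts$counts) && !counts$dup_corrected) {
    counts <- correct_dup_overlap(counts)
  }
  wt_q <- concentration_from_counts(counts, "WT", mode = "naive")
  rows <- list()
  for (g in setdiff(names(counts$counts), "WT")) {
    k_raw <- counts$counts[[g]]
    k_corr <- if (!is.null(mu_corr) && g %in% names(mu_corr)) {
      lob_correct_counts(k_raw, g, mu_corr)
    } else k_raw
    mode <- if (g %in% conditional_targets) "conditional" else "naive"
    q <- concentration_from_counts(counts, g, mode = mode, k = k_corr)
    maf <- if (q$copies_per_pcr + wt_q$copies_per_pcr > 0) {
      compute_maf(q$copies_per_pcr, wt_q$copies_per_pcr)
    } else NA_real_
    rows[[g]] <- data.frame(
      target = g, k_raw = k_raw, k_corrected = k_corr,
      lambda = q$lambda_per_droplet,
      copies_per_pcr = q$copies_per_pcr,
      copies_per_ml = if (!is.null(prep)) copies_per_ml_plasma(q, prep) else NA_real_,
      maf_pct = maf, ci_low = q$ci_low, ci_high = q$ci_high,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
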