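#' Corrected blank mean
#'
#' The expected false-positive droplet count per chamber for a detection
#' group, estimated conservatively from a blank panel as
#' `mu_corr = mu + 1.645 * sigma / sqrt(N)`, where `mu` and `sigma` are the
#' mean and sample SD (n - 1) of the false-positive counts and `N` the
#' number of blank replicates: the upper 95% confidence bound on the blank
#' mean.
#'
#' @param counts Integer vector of false-positive droplet counts from >= 2
#'   blank replicates.
#' @return The corrected mean (droplets per chamber).
#' @examples
#' corrected_blank_mean(c(1, 2, 3))  # 2 + 1.645/sqrt(3) = 2.9497
#' @export
corrected_blank_mean <- function(counts) {
  if (length(counts) < 2L) {
    .stopf("need >= 2 blank replicates (sample SD undefined otherwise)")
  }
  if (any(counts < 0)) .stopf("blank counts must be >= 0")
  mean(counts) + 1.645 * stats::sd(counts) / sqrt(length(counts))
}

#' Limit of blank (LOB95) in droplets
#'
#' The maximum number of false-positive droplets expected in a blank
#' chamber at 95% probability: the smallest integer `L` such that
#' `P(X > L) <= 0.05` for a count model with mean `mu_corr`. Both a normal
#' approximation (`L >= mu + 1.645 sqrt(mu)`) and the Chernoff bound for a
#' Poisson upper tail (`exp(-mu) (e mu / k)^k <= 0.05`) are evaluated; the
#' returned limit is the tighter admissible of the two. The exact Poisson
#' quantile is available as a verification method.
#'
#' @param mu_corr Corrected blank mean (>= 0).
#' @param method `"combined"` (default; tighter of normal and Chernoff),
#'   or one of `"normal"`, `"chernoff"`, `"exact"`.
#' @return Integer droplet count.
#' @examples
#' lob95(0)     # 0
#' lob95(2.28)  # 5
#' @export
lob95 <- function(mu_corr, method = c("combined", "normal", "chernoff", "exact")) {
  method <- match.arg(method)
  if (mu_corr < 0) .stopf("mu_corr must be >= 0")
  if (mu_corr == 0) return(0L)
  normal_l <- as.integer(ceiling(mu_corr + 1.645 * sqrt(mu_corr)))
  chernoff_l <- {
    k <- max(1L, as.integer(ceiling(mu_corr)))
    while (exp(-mu_corr) * (exp(1) * mu_corr / k)^k > 0.05) k <- k + 1L
    k - 1L
  }
  exact_l <- as.integer(stats::qpois(0.95, mu_corr))
  switch(method,
         combined = min(normal_l, chernoff_l),
         normal = normal_l,
         chernoff = chernoff_l,
         exact = exact_l)
}

#' Theoretical limit of detection (LOD95) in droplets
#'
#' The minimum mean positive-droplet count statistically distinguishable
#' from blank: the smallest integer mean `d` such that a Poisson count
#' with mean `d` exceeds the LOB (i.e. reaches `lob + 1` droplets) with
#' probability >= 95%.
#'
#' @param lob LOB95 in droplets (>= 0).
#' @param n_partitions,droplet_volume,reaction_volume Chamber geometry for
#'   the copies/PCR conversion (nL and uL).
#' @param background_copies Wild-type copies/PCR against which the MAF
#'   equivalent is expressed.
#' @return A list: `lod95_droplets`, `lod95_copies_per_pcr`,
#'   `lod95_maf_pct` (MAF equivalent at the background concentration).
#' @examples
#' lod95_theoretical(0)$lod95_droplets  # 3: P(X >= 1 | mean 3) = 0.9502
#' lod95_theoretical(5)$lod95_droplets  # 11
#' @export
lod95_theoretical <- function(lob, n_partitions = 20000,
                              droplet_volume = 0.68, reaction_volume = 25,
                              background_copies = 10000) {
  if (lob < 0) .stopf("lob must be >= 0")
  d <- lob
  repeat {
    d <- d + 1L
    if (stats::ppois(lob, d) <= 0.05) break
  }
  lambda <- -log(1 - d / n_partitions)
  copies <- lambda * (reaction_volume * 1000) / droplet_volume
  list(lod95_droplets = as.integer(d),
       lod95_copies_per_pcr = copies,
       lod95_maf_pct = compute_maf(copies, background_copies))
}

#' Estimate detection limits from a blank panel
#'
#' Per detection group: blank mean, SD, corrected mean
#' ([corrected_blank_mean()]), LOB95 ([lob95()]) and theoretical LOD95
#' ([lod95_theoretical()]), for the single-replicate assay.
#'
#' @param blanks A `blank_panel` (replicate-by-group count matrix) from
#'   [simulate_blank_panel()] or [read_blank_panel()].
#' @param n_partitions,droplet_volume,reaction_volume Chamber geometry.
#' @param background_copies Wild-type copies/PCR of the blank panel.
#' @return A data frame of class `limit_estimates`, one row per group:
#'   `group`, `n_replicates_assayed` (= 1), `mu`, `sigma`, `n_blanks`,
#'   `mu_corr`, `lob95_droplets`, `lod95_droplets`,
#'   `lod95_copies_per_pcr`, `lod95_maf_pct`.
#' @export
estimate_limits <- function(blanks, n_partitions = 20000,
                            droplet_volume = 0.68, reaction_volume = 25,
                            background_copies = 10000) {
  counts <- as.matrix(blanks)
  rows <- lapply(colnames(counts), function(g) {
    x <- counts[, g]
    mu_corr <- corrected_blank_mean(x)
    lob <- lob95(mu_corr)
    lod <- lod95_theoretical(lob, n_partitions, droplet_volume,
                             reaction_volume, background_copies)
    data.frame(group = g, n_replicates_assayed = 1L,
               mu = mean(x), sigma = stats::sd(x), n_blanks = length(x),
               mu_corr = mu_corr,
               lob95_droplets = lob,
               lod95_droplets = lod$lod95_droplets,
               lod95_copies_per_pcr = lod$lod95_copies_per_pcr,
               lod95_maf_pct = lod$lod95_maf_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("limit_estimates", "data.frame")
  attr(out, "geometry") <- list(n_partitions = n_partitions,
                                droplet_volume = droplet_volume,
                                reaction_volume = reaction_volume,
                                background_copies = background_copies)
  out
}

#' Detection limits for pooled-replicate assays
#'
#' For a sample assayed in `r` replicates the chambers are pooled: the
#' expected blank count scales to `r * mu_corr` and both LOB95 and LOD95
#' are recomputed on the pooled scale (pooled partitions `r * N`). Because
#' the Poisson tail tightens relative to its mean, the pooled LOD in
#' copies/PCR (equivalently MAF) is smaller than the single-replicate LOD
#' -- the sensitivity gain that motivates replication.
#'
#' @param single A `limit_estimates` table for the one-replicate assay.
#' @param r Replicate count (1 returns the input unchanged).
#' @return A `limit_estimates` table with `n_replicates_assayed = r`;
#'   droplet limits are on the pooled scale, copies/PCR and MAF are
#'   per-reaction concentrations.
#' @export
limits_for_replicates <- function(single, r) {
  stopifnot(inherits(single, "limit_estimates"))
  if (!r %in% c(1L, 2L, 3L)) .stopf("r must be 1, 2 or 3")
  if (r == 1L) return(single)
  geom <- attr(single, "geometry")
  out <- single
  out$n_replicates_assayed <- as.integer(r)
  for (i in seq_len(nrow(out))) {
    mu_pool <- r * single$mu_corr[i]
    lob <- lob95(mu_pool)
    lod <- lod95_theoretical(lob,
                             n_partitions = r * geom$n_partitions,
                             droplet_volume = geom$droplet_volume,
                             reaction_volume = geom$reaction_volume,
                             background_copies = geom$background_copies)
    out$mu_corr[i] <- mu_pool
    out$lob95_droplets[i] <- lob
    out$lod95_droplets[i] <- lod$lod95_droplets
    out$lod95_copies_per_pcr[i] <- lod$lod95_copies_per_pcr
    out$lod95_maf_pct[i] <- lod$lod95_maf_pct
  }
  attr(out, "geometry") <- geom
  out
}

#' Read / write blank panels as CSV
#'
#' Blank panels travel as long-format CSV with columns `group`,
#' `replicate`, `count`.
#'
#' @param blanks A `blank_panel` count matrix.
#' @param path File path.
#' @return `write_blank_panel()` returns `path` invisibly;
#'   `read_blank_panel()` returns a `blank_panel` matrix.
#' @export
write_blank_panel <- function(blanks, path) {
  counts <- as.matrix(blanks)
  long <- data.frame(group = rep(colnames(counts), each = nrow(counts)),
                     replicate = rep(seq_len(nrow(counts)), times = ncol(counts)),
                     count = as.vector(counts))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blank_panel
#' @export
read_blank_panel <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "replicate", "count")
  if (!all(need %in% names(long))) {
    .stopf("blank panel CSV needs columns: %s", paste(need, collapse = ", "))
  }
  groups <- unique(long$group)
  reps <- sort(unique(long$replicate))
  counts <- matrix(0L, nrow = length(reps), ncol = length(groups),
                   dimnames = list(NULL, groups))
  for (i in seq_len(nrow(long))) {
    counts[match(long$replicate[i], reps), long$group[i]] <- long$count[i]
  }
  structure(counts, class = c("blank_panel", class(counts)),
            n_replicates = length(reps), background_copies = NA_real_)
}
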