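# Shared fixtures, built once per test run. Everything is generated in
# code; seeds are fixed so all expectations are reproducible.

.fx <- new.env(parent = emptyenv())

fx_assays <- function() {
  if (is.null(.fx$assays)) .fx$assays <- build_erbb2_assays()
  .fx$assays
}

fx_design <- function() fx_assays()$screening

# Template mix of a screening positive control: wild-type gDNA plus
# mutant gBlocks covering every positive cluster.
fx_control_templates <- function() {
  c(WT = 5000, S310F = 400, S310Y = 400, L755S = 400, D769H = 400,
    D769Y = 400, L869R = 400, Y772_A775dup = 400, G778_P780dup_1 = 300,
    G778_P780dup_2 = 300, G776V = 300, V777L_GtoT = 300)
}

fx_pos_control <- function() {
  if (is.null(.fx$pos_control)) {
    .fx$pos_control <- simulate_chamber(
      chamber_config(fx_control_templates(), seed = 100, chamber_id = "posctrl"),
      fx_design())
  }
  .fx$pos_control
}

fx_neg_control <- function() {
  if (is.null(.fx$neg_control)) {
    .fx$neg_control <- simulate_chamber(
      chamber_config(c(WT = 0), seed = 101, chamber_id = "negctrl"),
      fx_design())
  }
  .fx$neg_control
}

fx_gates <- function() {
  if (is.null(.fx$gates)) .fx$gates <- derive_gates(fx_pos_control(), fx_design())
  .fx$gates
}

# Analytic single-replicate limits at the design's calibrated blank
# false-positive rates (34-replicate panel of Poisson blanks).
fx_limits <- function() {
  if (is.null(.fx$limits)) {
    fp <- fx_design()$fp_rate
    mu_corr <- fp + 1.645 * sqrt(fp) / sqrt(34)
    rows <- lapply(names(fp), function(g) {
      lob <- lob95(mu_corr[[g]])
      lod <- lod95_theoretical(lob)
      data.frame(group = g, n_replicates_assayed = 1L,
                 mu = fp[[g]], sigma = sqrt(fp[[g]]), n_blanks = 34L,
                 mu_corr = mu_corr[[g]], lob95_droplets = lob,
                 lod95_droplets = lod$lod95_droplets,
                 lod95_copies_per_pcr = lod$lod95_copies_per_pcr,
                 lod95_maf_pct = lod$lod95_maf_pct,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("limit_estimates", "data.frame")
    attr(out, "geometry") <- list(n_partitions = 20000, droplet_volume = 0.68,
                                  reaction_volume = 25, background_copies = 10000)
    .fx$limits <- out
  }
  .fx$limits
}

# A screening sample: n_rep replicate chambers at the given template mix.
make_sample <- function(templates, seed, n_rep = 1L) {
  lapply(seq_len(n_rep), function(i) {
    simulate_chamber(chamber_config(templates, seed = seed + i,
                                    chamber_id = sprintf("s%d_%d", seed, i)),
                     fx_design())
  })
}

# A duplex design with gates derived from its own positive control.
make_duplex_kit <- function(name, mut_template, seed) {
  ddesign <- fx_assays()$duplexes[[name]]
  ctrl <- simulate_chamber(
    chamber_config(stats::setNames(c(4000, 2000), c("WT", mut_template)),
                   seed = seed, chamber_id = paste0(name, "_ctrl")), ddesign)
  list(design = ddesign, gates = derive_gates(ctrl, ddesign))
}

# Minimal cluster_counts object for estimator tests at a given k and N.
fx_counts <- function(k, N = 20000, wt = NULL, extra = NULL) {
  counts <- c("776-779_MUT" = k)
  if (!is.null(wt)) counts <- c(counts, WT = wt)
  if (!is.null(extra)) counts <- c(counts, extra)
  structure(list(chamber_id = "synthetic", total_partitions = N,
                 counts = counts, assigned = NULL,
                 n_classified = sum(counts), n_empty = N - sum(counts),
                 unclassified = 0L, droplet_volume = 0.68,
                 reaction_volume = 25, design = "ERBB2_S",
                 dup_corrected = TRUE),
            class = "cluster_counts")
}
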