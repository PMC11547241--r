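test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  for (rep in 1:5) {
    # random simple polygon (star-shaped around its centroid)
    nv <- sample(3:8, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    r <- stats::runif(nv, 0.5, 2)
    poly <- cbind(r * cos(ang), r * sin(ang))
    x <- stats::runif(200, -2.5, 2.5)
    y <- stats::runif(200, -2.5, 2.5)
    ours <- point_in_polygon(x, y, poly)
    ref <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(x, y))
    # implementations may differ exactly on the boundary; none of these
    # random points are on it
    expect_equal(ours, as.logical(ref))
  }
})

test_that("polygon boundary points count as inside", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(all(point_in_polygon(c(0, 0.5, 1, 0.5), c(0.5, 0, 0.5, 1), sq)))
  expect_true(point_in_polygon(0.5, 0.5, sq))
  expect_false(point_in_polygon(1.5, 0.5, sq))
  expect_error(point_in_polygon(0, 0, cbind(0, 1)), ">= 3")
})

test_that("derive_gates builds one polygon per detection class and demands a full control", {
  gates <- fx_gates()
  expect_length(gates$gates, 5L)
  expect_setequal(names(gates$gates),
                  vapply(fx_design()$gate_defs, `[[`, character(1), "name"))

  # a control without duplication clusters must fail, naming the class
  tpl <- fx_control_templates()
  tpl[c("Y772_A775dup", "G778_P780dup_1", "G778_P780dup_2")] <- 0
  partial <- simulate_chamber(chamber_config(tpl, seed = 33, chamber_id = "pc2"),
                              fx_design())
  expect_error(derive_gates(partial, fx_design()), "Y772_A775dup-G778_P780dup")

  # an empty control has no usable clusters at all
  empty <- simulate_chamber(chamber_config(c(WT = 0), seed = 34, chamber_id = "e"),
                            fx_design())
  expect_error(derive_gates(empty, fx_design()),
               "missing cluster|no separated positive cluster")
})

test_that("classification recovers provenance on non-rain droplets (>= 99%)", {
  ds <- fx_pos_control()
  gates <- fx_gates()
  cc <- classify_droplets(ds, gates)
  prov <- attr(ds, "provenance")
  design <- fx_design()
  expected <- dropscreen:::.expected_gates_by_signature(design)
  keep <- !prov$rained & is.na(prov$fp_group)
  ok <- vapply(which(keep), function(i) {
    exp_gates <- expected[[prov$true_signature[i]]]
    if (!length(exp_gates)) is.na(cc$assigned[i]) else cc$assigned[i] %in% exp_gates
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("droplet conservation holds before and after dup correction", {
  ds <- fx_pos_control()
  cc <- classify_droplets(ds, fx_gates())
  expect_equal(cc$n_classified + cc$unclassified + cc$n_empty,
               cc$total_partitions)
  cc2 <- correct_dup_overlap(cc)
  expect_equal(cc2$n_classified + cc2$unclassified + cc2$n_empty,
               cc2$total_partitions)
  # after correction the per-gate counts sum to the unique classified
  # tally, up to the rare droplets co-encapsulating mutants of two
  # different amplicons (counted on two planes)
  expect_gte(sum(cc2$counts), cc2$n_classified - 1)
  expect_lt(sum(cc2$counts) - cc2$n_classified, 0.005 * cc2$total_partitions)
})

test_that("noise-free chambers classify exactly as provenance", {
  design <- fx_design()
  cfg <- chamber_config(c(WT = 4000, V777L_GtoT = 300,
                          Y772_A775dup = 300, S310F = 300),
                        n_partitions = 8000, rain_fraction = 0, noise_sd = 0,
                        fp_rate = c("776-779_MUT" = 0), seed = 21)
  ds <- simulate_chamber(cfg, design)
  ctrl <- simulate_chamber(chamber_config(fx_control_templates(), rain_fraction = 0,
                                          noise_sd = 0, seed = 22,
                                          chamber_id = "nfctrl"), design)
  gates <- derive_gates(ctrl, design)
  cc <- correct_dup_overlap(classify_droplets(ds, gates))
  prov <- attr(ds, "provenance")
  truth <- table(factor(prov$true_class, levels = names(cc$counts)))
  # dup-corrected WT excludes triple positives, matching decode classes
  expect_equal(unname(cc$counts["WT"]), unname(truth[["WT"]]))
  expect_equal(unname(cc$counts["776-779_MUT"]),
               sum(prov$true_class %in% c("776-779_MUT", "776-779_MUT+dup")))
  expect_equal(unname(cc$counts["Y772_A775dup-G778_P780dup"]),
               unname(truth[["Y772_A775dup-G778_P780dup"]]))
  expect_equal(unname(cc$counts["S310F/Y"]), unname(truth[["S310F/Y"]]))
})

test_that("gate classification is invariant under affine intensity rescaling", {
  design <- fx_design()
  ds <- simulate_chamber(chamber_config(c(WT = 5000, V777L_GtoT = 200), seed = 44),
                         design)
  ctrl <- fx_pos_control()
  cc_ref <- classify_droplets(ds, derive_gates(ctrl, design))
  rescale <- function(d, a, b) {
    for (ch in c("FAM", "HEX", "Cy5")) d[[ch]] <- a * d[[ch]] + b
    d
  }
  ds2 <- rescale(ds, 2.5, 300)
  ctrl2 <- rescale(ctrl, 2.5, 300)
  cc_scaled <- classify_droplets(ds2, derive_gates(ctrl2, design))
  expect_equal(cc_scaled$counts, cc_ref$counts)
  expect_equal(cc_scaled$unclassified, cc_ref$unclassified)
})

test_that("dup superposition correction removes dup droplets from the WT gate", {
  cc <- fx_counts(0, N = 20000, wt = 5000,
                  extra = c("Y772_A775dup-G778_P780dup" = 100))
  cc$dup_corrected <- FALSE
  out <- correct_dup_overlap(cc)
  expect_equal(unname(out$counts[["WT"]]), 4900)
  expect_equal(unname(out$counts[["Y772_A775dup-G778_P780dup"]]), 100)

  cc0 <- fx_counts(0, N = 20000, wt = 5000,
                   extra = c("Y772_A775dup-G778_P780dup" = 0))
  cc0$dup_corrected <- FALSE
  expect_equal(unname(correct_dup_overlap(cc0)$counts[["WT"]]), 5000)

  ccf <- fx_counts(0, N = 20000, wt = 10,
                   extra = c("Y772_A775dup-G778_P780dup" = 50))
  ccf$dup_corrected <- FALSE
  expect_warning(out2 <- correct_dup_overlap(ccf), "flooring")
  expect_equal(unname(out2$counts[["WT"]]), 0)
})

test_that("gate sets round-trip through JSON and reproduce counts", {
  gates <- fx_gates()
  path <- withr::local_tempfile(fileext = ".json")
  write_gates(gates, path)
  back <- read_gates(path)
  ds <- simulate_chamber(chamber_config(c(WT = 3000), seed = 55), fx_design())
  expect_equal(classify_droplets(ds, back)$counts,
               classify_droplets(ds, gates)$counts)
})
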