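test_that("reaction planning applies the 33 ng cap and the 10 ng floor", {
  # 66 ng in the 15 uL input must be halved to reach the 33 ng cap
  expect_equal(plan_reaction(66 / 15)$dilution_factor, 2)
  # 33 ng/PCR corresponds to 10,000 copies at 3.3 pg per genome
  expect_equal(plan_reaction(33 / 15)$projected_copies_per_pcr, 10000)
  # 4 ng per input: three replicates reach 12 ng >= 10 ng
  p <- plan_reaction(4 / 15)
  expect_equal(p$n_replicates, 3L)
  expect_equal(p$total_ng_assayed, 12)
  # concentrated samples need no replication
  expect_equal(plan_reaction(30 / 15)$n_replicates, 1L)
  # material exhaustion caps replication
  expect_equal(plan_reaction(4 / 15, available_ul = 20)$n_replicates, 1L)
  expect_error(plan_reaction(-1), ">= 0")
  # projection never exceeds the 10,000 copies/PCR cap
  expect_lte(plan_reaction(500)$projected_copies_per_pcr, 10000)
})

test_that("the replicate positivity rule is applied per branch", {
  lim <- c(lob = 3, lod = 5)
  expect_equal(call_detection_group(c(6, 7, 2), lim)$status, "positive")
  expect_equal(call_detection_group(c(1, 0), c(lob = 3, lod = 8))$status, "negative")
  eq <- call_detection_group(4, c(lob = 3, lod = 8))
  expect_equal(eq$status, "equivocal")
  expect_match(eq$recommendation, "2 more")
  # single replicate at or above LOD is positive pending confirmation
  one <- call_detection_group(9, c(lob = 3, lod = 8))
  expect_equal(one$status, "positive")
  expect_match(one$recommendation, "duplex")
  # two of three at LOD wins even with one blank replicate
  expect_equal(call_detection_group(c(5, 5, 0), lim)$status, "positive")
  # one of two at LOD is not yet positive
  two <- call_detection_group(c(6, 2), c(lob = 3, lod = 5))
  expect_equal(two$status, "equivocal")
  expect_match(two$recommendation, "1 more")
  # limits can come from a limit_estimates table
  lims <- fx_limits()
  cl <- call_detection_group(c(20, 20), lims, group = "776-779_MUT")
  expect_equal(cl$status, "positive")
  expect_error(call_detection_group(c(1), lims, group = "nope"), "no limits")
})

test_that("two-step strategy identifies a V777L sample and clears a blank", {
  assays <- fx_assays()
  controls <- list(negative = fx_neg_control(), positive = fx_pos_control())
  kit <- make_duplex_kit("V777L", "V777L_GtoT", 500)
  prep <- sample_prep(plasma_volume = 4)

  # V777L at ~8.7% MAF (the high-signal regime of the worked examples)
  screen <- make_sample(c(WT = 10000, V777L_GtoT = 950), seed = 600)
  dup_ds <- simulate_chamber(
    chamber_config(c(WT = 10000, V777L_GtoT = 950), seed = 601,
                   chamber_id = "v777l_dx"), kit$design)
  call <- run_two_step(screen, list(V777L = list(dup_ds)),
                       controls = controls, assays = assays,
                       gates = fx_gates(),
                       duplex_gates = list(V777L = kit$gates),
                       limits = fx_limits(), prep = prep, sample_id = "V777L8.7")
  expect_true(call$controls_ok)
  expect_equal(call$status, "ok")
  expect_equal(call$identified$mutation, "V777L")
  screen_maf <- call$screen$maf_pct[call$screen$group == "776-779_MUT"]
  # screening MAF and duplex MAF agree within a factor of two
  expect_lt(abs(log2(call$identified$maf_pct / screen_maf)), 1)
  expect_lt(abs(call$identified$maf_pct - 8.7) / 8.7, 0.3)

  # a blank sample calls every group negative
  blank <- make_sample(c(WT = 10000), seed = 700, n_rep = 2L)
  bcall <- run_two_step(blank, list(), controls = controls, assays = assays,
                        gates = fx_gates(), limits = fx_limits(),
                        prep = prep, sample_id = "blank")
  expect_equal(bcall$status, "negative")
  expect_equal(nrow(bcall$identified), 0L)
  expect_true(all(bcall$screen$status == "negative"))
})

test_that("a double mutation yields two identifications from one sample", {
  assays <- fx_assays()
  controls <- list(negative = fx_neg_control(), positive = fx_pos_control())
  kits <- list(L755S = make_duplex_kit("L755S", "L755S", 510),
               D769H = make_duplex_kit("D769H", "D769H", 520))
  tpl <- c(WT = 10000, L755S = 300, D769H = 200)
  screen <- make_sample(tpl, seed = 800)
  duplexes <- list(
    L755S = list(simulate_chamber(chamber_config(tpl, seed = 801,
                                                 chamber_id = "dxl"),
                                  kits$L755S$design)),
    D769H = list(simulate_chamber(chamber_config(tpl, seed = 802,
                                                 chamber_id = "dxd"),
                                  kits$D769H$design)))
  call <- run_two_step(screen, duplexes, controls = controls, assays = assays,
                       gates = fx_gates(),
                       duplex_gates = list(L755S = kits$L755S$gates,
                                           D769H = kits$D769H$gates),
                       limits = fx_limits(), sample_id = "double")
  expect_equal(call$status, "ok")
  expect_setequal(call$identified$mutation, c("L755S", "D769H"))
  # both identifications come from the same positive screening group
  expect_true(all(call$identified$group == "L755S-D769H/Y-L869R"))
})

test_that("failed controls suppress calls; missing duplex data is flagged", {
  assays <- fx_assays()
  # a contaminated negative control (mutant template present) fails the run
  bad_neg <- simulate_chamber(
    chamber_config(c(WT = 0, V777L_GtoT = 500), seed = 900,
                   chamber_id = "badneg"), fx_design())
  screen <- make_sample(c(WT = 10000), seed = 910)
  call <- run_two_step(screen, list(),
                       controls = list(negative = bad_neg,
                                       positive = fx_pos_control()),
                       assays = assays, gates = fx_gates(),
                       limits = fx_limits(), sample_id = "badrun")
  expect_false(call$controls_ok)
  expect_equal(call$status, "invalid-controls")
  expect_null(call$identified)

  # positive screen without duplex chambers cannot be completed
  pos_screen <- make_sample(c(WT = 10000, V777L_GtoT = 950), seed = 920)
  inc <- run_two_step(pos_screen, list(),
                      controls = list(negative = fx_neg_control(),
                                      positive = fx_pos_control()),
                      assays = assays, gates = fx_gates(),
                      limits = fx_limits(), sample_id = "noduplex")
  expect_equal(inc$status, "incomplete")
})

test_that("no identification can bypass a positive screen", {
  # structural invariant of the caller: identified mutations always trace
  # back to a positive screening group
  assays <- fx_assays()
  kit <- make_duplex_kit("V777L", "V777L_GtoT", 530)
  # the screening sample is blank, the duplex chamber (incorrectly) is not:
  # the caller must not consult it
  screen <- make_sample(c(WT = 10000), seed = 930)
  rogue_dup <- simulate_chamber(
    chamber_config(c(WT = 10000, V777L_GtoT = 900), seed = 931,
                   chamber_id = "rogue"), kit$design)
  call <- run_two_step(screen, list(V777L = list(rogue_dup)),
                       controls = list(negative = fx_neg_control(),
                                       positive = fx_pos_control()),
                       assays = assays, gates = fx_gates(),
                       duplex_gates = list(V777L = kit$gates),
                       limits = fx_limits(), sample_id = "rogue")
  expect_equal(call$status, "negative")
  expect_equal(nrow(call$identified), 0L)
})

test_that("group calls are accurate on simulated samples at MAF >= 1%", {
  design <- fx_design()
  lims <- fx_limits()
  lod <- lims$lod95_droplets[lims$group == "776-779_MUT"]
  lob <- lims$lob95_droplets[lims$group == "776-779_MUT"]
  n_pos <- 60; n_neg <- 60
  pos_calls <- vapply(seq_len(n_pos), function(i) {
    ds <- simulate_chamber(chamber_config(c(WT = 10000, V777L_GtoT = 100),
                                          seed = 1000 + i,
                                          chamber_id = paste0("pp", i)), design)
    cc <- classify_droplets(ds, fx_gates())
    call_detection_group(cc$counts[["776-779_MUT"]],
                         c(lob = lob, lod = lod))$status
  }, character(1))
  neg_calls <- vapply(seq_len(n_neg), function(i) {
    ds <- simulate_chamber(chamber_config(c(WT = 10000), seed = 2000 + i,
                                          chamber_id = paste0("nn", i)), design)
    cc <- classify_droplets(ds, fx_gates())
    call_detection_group(cc$counts[["776-779_MUT"]],
                         c(lob = lob, lod = lod))$status
  }, character(1))
  expect_equal(mean(pos_calls == "positive"), 1)        # sensitivity at 1% MAF
  expect_gte(mean(neg_calls == "negative"), 0.95)       # specificity
  expect_equal(mean(neg_calls == "positive"), 0)        # no blank called positive
})
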