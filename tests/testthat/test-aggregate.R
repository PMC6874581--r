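test_that("bead normalization rescales exactly the optical channels", {
  ev <- random_events(10)
  out <- normalize_channels(ev, c(fsc = 2, red = 4, orange = 8))
  expect_equal(out$fsc, ev$fsc / 2)
  expect_equal(out$red, ev$red / 4)
  expect_equal(out$orange, ev$orange / 8)
  expect_equal(out$d1, ev$d1)
})

test_that("summary quantiles follow the linear-interpolation convention", {
  core <- virtual_core_volume(0.5, data.frame(file_id = "f", flow_rate = 1,
                                              flow_rate_se = 0.05, duration = 60))
  opp <- data.frame(d1 = 1, d2 = 1, fsc = c(1, 2, 3), red = c(3, 1, 2),
                    orange = c(2, 3, 1))
  lab <- factor(rep("synecho", 3), levels = cytocore:::POPULATION_LEVELS)
  esd <- list("1.38" = c(1, 2, 3))
  qc <- list("1.38" = carbon_from_volume(esd_to_volume(c(1, 2, 3))))
  s <- summarize_file(lab, opp, esd, qc, core)
  expect_equal(nrow(s), 1)
  expect_equal(s$fsc_med, 2); expect_equal(s$fsc_q25, 1.5); expect_equal(s$fsc_q75, 2.5)
  expect_equal(s$esd_n138_med, 2)
  expect_equal(s$n, 3)
  # a population of one particle collapses the quartiles
  one <- summarize_file(factor("croco", levels = cytocore:::POPULATION_LEVELS),
                        opp[1, ], list("1.38" = 1), list("1.38" = 0.2), core)
  expect_equal(one$fsc_med, one$fsc_q25)
  expect_equal(one$fsc_med, one$fsc_q75)
})

test_that("per-population counts partition the OPP minus unknowns", {
  sim <- small_sim()
  fp <- small_filtration()
  ev <- sim$events[[2]]
  opp <- select_opp(ev, fp, 50)
  core <- virtual_core_volume(opp_ratio(opp, ev),
                              sim$metadata[sim$metadata$file_id == ev$file_id[1], ])
  bead_rows <- cytocore:::gate_members(opp, sim$gating$bead_gate_raw$channels,
                                       sim$gating$bead_gate_raw$polygon)
  ref <- vapply(c("fsc", "red", "orange"),
                function(ch) median(opp[[ch]][bead_rows]), numeric(1))
  opp_n <- normalize_channels(opp, ref)
  labels <- classify_populations(opp_n, sim$gating)
  esd <- list("1.38" = rep(1, nrow(opp)))
  qc <- list("1.38" = rep(0.2, nrow(opp)))
  s_no <- summarize_file(labels, opp_n, esd, qc, core)
  expect_equal(sum(s_no$n), nrow(opp) - sum(labels == "unknown"))
  s_yes <- summarize_file(labels, opp_n, esd, qc, core, include_unknown = TRUE)
  expect_equal(sum(s_yes$n), nrow(opp))
  # quantile ordering holds for every emitted triple
  for (ch in c("fsc", "red", "orange", "esd_n138", "carbon_n138")) {
    expect_true(all(s_yes[[paste0(ch, "_q25")]] <= s_yes[[paste0(ch, "_med")]]))
    expect_true(all(s_yes[[paste0(ch, "_med")]] <= s_yes[[paste0(ch, "_q75")]]))
  }
})

test_that("metadata merge preserves rows, nulls and referential integrity", {
  sim <- small_sim()
  meta <- sim$metadata
  meta$salinity[1] <- NA
  summaries <- data.frame(file_id = rep(meta$file_id, each = 2),
                          population = c("prochloro", "synecho"),
                          n = 5, abundance = 1, abundance_se = 0.1,
                          stringsAsFactors = FALSE)
  out <- merge_metadata(summaries, meta)
  expect_equal(nrow(out), nrow(summaries))
  expect_true(all(is.na(out$salinity[out$file_id == meta$file_id[1]])))
  expect_equal(out$cruise, rep(meta$cruise_id, each = 2))
  expect_error(merge_metadata(rbind(summaries,
    data.frame(file_id = "ghost", population = "croco", n = 1,
               abundance = 1, abundance_se = 0.1)), meta), "ghost")
})
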