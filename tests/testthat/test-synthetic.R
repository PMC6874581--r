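test_that("the simulator is deterministic down to the emitted bytes", {
  d1 <- tempfile("sim_a"); d2 <- tempfile("sim_b")
  cfg <- sim_config(seed = 3, n_files = 1, duration = 10, mie = list(grid_n = 300))
  simulate_cruise(cfg, dir = d1)
  simulate_cruise(cfg, dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("event counts follow the configured Poisson rate", {
  cfg <- sim_config(seed = 8, n_files = 6, duration = 60, mie = list(grid_n = 300))
  sim <- simulate_cruise(cfg)
  rate <- (sum(cfg$populations$concentration) + cfg$bead$concentration) *
    cfg$flow_rate * 1000 / 60
  expected <- rate * cfg$duration
  for (ev in sim$events) {
    expect_lt(abs(nrow(ev) - expected) / sqrt(expected), 3)
  }
  # empirical per-file rate is what the metadata reports
  expect_equal(sim$metadata$event_rate,
               vapply(sim$events, nrow, integer(1), USE.NAMES = FALSE) / 60)
})

test_that("a beads-only ocean yields no biological populations", {
  pops <- default_populations()
  pops$concentration <- 0
  cfg <- sim_config(seed = 5, n_files = 1, duration = 30,
                    populations = pops, mie = list(grid_n = 300))
  sim <- simulate_cruise(cfg)
  expect_true(all(sim$truth$particles$population == "beads"))
  ev <- sim$events[[1]]
  mask <- cytocore:::gate_members(ev, sim$gating$bead_gate_raw$channels,
                                  sim$gating$bead_gate_raw$polygon)
  expect_gte(mean(mask), 0.99)
})

test_that("particles inside the core fraction are accepted as OPP at 50%", {
  sim <- small_sim()
  fp <- small_filtration()
  cfg <- sim$config
  for (fid in names(sim$events)) {
    ev <- sim$events[[fid]]
    tr <- sim$truth$particles[sim$truth$particles$file_id == fid, ]
    ev$rowid <- seq_len(nrow(ev))
    opp <- select_opp(ev, fp, 50)
    core_rows <- which(tr$r < cfg$core$core_radius_fraction)
    expect_gte(mean(core_rows %in% opp$rowid), 0.95)
  }
})

test_that("truth labels agree with pipeline labels at decade separation", {
  sim <- small_sim()
  fp <- small_filtration()
  ev <- do.call(rbind, sim$events)
  tr <- sim$truth$particles
  ev$truth <- tr$population
  opp <- select_opp(ev, fp, 50)
  bead_rows <- cytocore:::gate_members(opp, sim$gating$bead_gate_raw$channels,
                                       sim$gating$bead_gate_raw$polygon)
  ref <- vapply(c("fsc", "red", "orange"),
                function(ch) median(opp[[ch]][bead_rows]), numeric(1))
  labels <- classify_populations(normalize_channels(opp, ref), sim$gating)
  agree <- mean(as.character(labels) == opp$truth)
  expect_gte(agree, 0.99)
})

test_that("invalid configurations fail before any file is written", {
  pops <- default_populations()
  pops$concentration[1] <- -5
  expect_error(sim_config(populations = pops))
  expect_error(sim_config(flow_rate = 0))
  expect_error(sim_config(core = list(gain_center = 0.3, gain_width = 1,
                                      lateral_sensitivity = 0.5,
                                      core_radius_fraction = 1.5)))
})

test_that("injected QC faults surface in the metadata", {
  cfg <- sim_config(seed = 2, n_files = 3, duration = 10, mie = list(grid_n = 300),
                    qc_faults = list(pressure_files = 2, pressure_dev = 0.3,
                                     rate_files = 3, rate_value = 25000))
  sim <- simulate_cruise(cfg)
  fl <- flag_instrument(sim$metadata)
  expect_identical(fl$flag_pressure[2], 1L)
  expect_identical(fl$flag_rate, c(0L, 0L, 1L))
})
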