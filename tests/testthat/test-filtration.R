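# Beads lying exactly on a known line through the anchor must be recovered
# by the anchored quantile regressions.
test_that("anchored fit recovers a known bead line", {
  set.seed(1)
  n <- 400
  lfsc <- c(runif(n / 2, 1, 2.9), runif(n / 2, 3.1, 5))  # anchor at 3
  anchor <- c(fsc = 3, d = 2)
  ld <- anchor["d"] + 0.5 * (lfsc - anchor["fsc"]) + rnorm(n, 0, 1e-4)
  ev <- data.frame(d1 = 10^ld, d2 = 10^ld, fsc = 10^lfsc,
                   red = 1, orange = 1)
  # pad with median-anchoring rows so the median equals the true anchor
  ev <- rbind(ev, data.frame(d1 = 10^2, d2 = 10^2, fsc = 10^3, red = 1,
                             orange = 1)[rep(1, n), ])
  fp <- fit_filtration_params(ev, rep(TRUE, nrow(ev)))
  s50 <- fp$slopes$slope[fp$slopes$quantile == 50]
  expect_true(all(abs(s50 - 0.5) < 0.01))
  expect_equal(unname(fp$anchor["fsc"]), 3, tolerance = 1e-6)
})

test_that("requesting a single quantile yields only that quantile's slopes", {
  sim <- small_sim()
  ev <- do.call(rbind, sim$events)
  mask <- cytocore:::gate_members(ev, sim$gating$bead_gate_raw$channels,
                                  sim$gating$bead_gate_raw$polygon)
  fp <- fit_filtration_params(ev, mask, quantiles = 50)
  expect_equal(unique(fp$slopes$quantile), 50)
  expect_error(select_opp(ev, fp, 2.5), "unknown quantile")
})

test_that("fitted slopes minimize the pinball loss (grid-search oracle)", {
  set.seed(7)
  n <- 300
  x <- c(runif(n, -2, -0.05), runif(n, 0.05, 2))
  y <- 0.8 * x + rnorm(2 * n, 0, 0.2)
  for (tau in c(0.025, 0.5, 0.975)) {
    for (side in c("below", "above")) {
      sel <- if (side == "below") x < 0 else x > 0
      fitted <- cytocore:::anchored_qr_slope(x[sel], y[sel], tau)
      grid <- seq(-1, 3, by = 1e-3)
      losses <- vapply(grid, pinball_loss, numeric(1), x = x[sel], y = y[sel], tau = tau)
      oracle <- grid[which.min(losses)]  # ties toward the smaller slope
      expect_lt(abs(fitted - oracle), 2e-3)
    }
  }
})

test_that("degenerate bead inputs are rejected", {
  ev <- random_events(100)
  expect_error(fit_filtration_params(ev, rep(c(TRUE, FALSE), c(10, 90))),
               "too few")
  flat <- data.frame(d1 = 1, d2 = 1, fsc = 1, red = 1, orange = 1)[rep(1, 100), ]
  expect_error(fit_filtration_params(flat, rep(TRUE, 100)), "degenerate")
})

test_that("OPP predicates match a per-row scalar oracle and respect alignment", {
  fp <- small_filtration()
  set.seed(11)
  n <- 10000
  ev <- data.frame(d1 = rlnorm(n, 5, 2), d2 = rlnorm(n, 5, 2),
                   fsc = rlnorm(n, 7, 2), red = rlnorm(n), orange = rlnorm(n),
                   rowid = seq_len(n))
  opp <- select_opp(ev, fp, 50)
  # independent scalar re-evaluation of the three predicates
  bound <- function(det, q, lf) {
    s <- fp$slopes
    x <- lf - fp$anchor["fsc"]
    b <- s$slope[s$detector == det & s$quantile == q &
                   s$segment == (if (x < 0) "below" else "above")]
    unname(fp$anchor[det] + b * x)
  }
  scalar <- vapply(seq_len(n), function(i) {
    l1 <- log10(ev$d1[i]); l2 <- log10(ev$d2[i]); lf <- log10(ev$fsc[i])
    abs(l1 - l2) <= fp$alignment_tol &&
      l1 <= bound("d1", 50, lf) && l2 <= bound("d2", 50, lf)
  }, logical(1))
  expect_identical(which(scalar), opp$rowid)
  # particle at the exact anchor lies on every boundary, so it is accepted
  anchor_particle <- data.frame(d1 = 10^fp$anchor["d1"], d2 = 10^fp$anchor["d2"],
                                fsc = 10^fp$anchor["fsc"], red = 1, orange = 1)
  expect_equal(nrow(select_opp(anchor_particle, fp, 97.5)), 1L)
  expect_equal(nrow(select_opp(anchor_particle, fp, 50)), 1L)
  # gross misalignment is rejected at all quantiles
  bad <- data.frame(d1 = 1e6, d2 = 1, fsc = 10^fp$anchor["fsc"], red = 1, orange = 1)
  for (q in fp$quantiles) expect_equal(nrow(select_opp(bad, fp, q)), 0L)
})

test_that("quantile sets are nested and ratios monotone on simulated files", {
  sim <- small_sim()
  fp <- small_filtration()
  for (ev in sim$events) {
    ids <- lapply(c(2.5, 50, 97.5), function(q) {
      opp <- select_opp(cbind(ev, rowid = seq_len(nrow(ev))), fp, q)
      opp$rowid
    })
    expect_true(all(ids[[1]] %in% ids[[2]]))
    expect_true(all(ids[[2]] %in% ids[[3]]))
    r <- vapply(ids, function(i) length(i) / nrow(ev), numeric(1))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("OPP membership is equivariant under a common channel rescaling", {
  sim <- small_sim()
  ev <- sim$events[[1]]
  ev$rowid <- seq_len(nrow(ev))
  all_ev <- do.call(rbind, sim$events)
  mask <- cytocore:::gate_members(all_ev, sim$gating$bead_gate_raw$channels,
                                  sim$gating$bead_gate_raw$polygon)
  scale_events <- function(e, k) {
    for (ch in c("d1", "d2", "fsc", "red", "orange")) e[[ch]] <- e[[ch]] * k
    e
  }
  fp1 <- fit_filtration_params(all_ev, mask)
  fp2 <- fit_filtration_params(scale_events(all_ev, 7), mask)
  o1 <- select_opp(ev, fp1, 50)
  o2 <- select_opp(scale_events(ev, 7), fp2, 50)
  expect_identical(o1$rowid, o2$rowid)
})

test_that("opp_ratio is the plain fraction and rejects empty inputs", {
  ev <- random_events(1000)
  expect_equal(opp_ratio(ev[1:100, ], ev), 0.1)
  expect_equal(opp_ratio(ev, ev), 1)
  expect_error(opp_ratio(ev[0, ], ev[0, ]), "empty")
})
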