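simple_spec <- function() {
  box <- function(cx, cy, h) matrix(c(cx - h, cy - h, cx + h, cy - h,
                                      cx + h, cy + h, cx - h, cy + h),
                                    ncol = 2, byrow = TRUE)
  gating_spec(
    gates = list(beads = list(channels = c("fsc", "orange"), polygon = box(0, 0, 1)),
                 synecho = list(channels = c("fsc", "orange"), polygon = box(0.5, 0.5, 1))),
    picoeuk_thresholds = c(fsc = 0, red = 0))
}

test_that("sequential gates give priority to the earlier polygon", {
  spec <- simple_spec()
  # point inside both the beads and synecho polygons -> beads wins
  both <- data.frame(d1 = 1, d2 = 1, fsc = 10^0.5, red = 1, orange = 10^0.5)
  expect_equal(apply_manual_gates(both, spec), "beads")
  only_syn <- data.frame(d1 = 1, d2 = 1, fsc = 10^1.2, red = 1, orange = 10^1.2)
  expect_equal(apply_manual_gates(only_syn, spec), "synecho")
  outside <- data.frame(d1 = 1, d2 = 1, fsc = 10^4, red = 1, orange = 10^4)
  expect_true(is.na(apply_manual_gates(outside, spec)))
})

test_that("self-intersecting polygons are rejected at spec load", {
  bow <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(gating_spec(list(beads = list(channels = c("fsc", "orange"),
                                             polygon = bow)),
                           picoeuk_thresholds = c(fsc = 0, red = 0)),
               "self-intersecting")
})

test_that("polygon membership agrees with a ray-casting oracle", {
  set.seed(5)
  for (rep in 1:10) {
    poly <- random_star_polygon(k = sample(4:9, 1))
    pts <- cbind(runif(1000, -2.5, 2.5), runif(1000, -2.5, 2.5))
    got <- cytocore:::gate_members(
      data.frame(fsc = 10^pts[, 1], red = 10^pts[, 2]),
      c("fsc", "red"), poly)
    want <- vapply(seq_len(nrow(pts)),
                   function(i) ray_cast_inside(pts[i, 1], pts[i, 2], poly),
                   logical(1))
    # boundary-grazing points may differ legitimately; none are expected
    # for random continuous points
    expect_equal(got, want)
  }
})

test_that("density clusterer captures a single well-separated mode", {
  set.seed(9)
  pool <- data.frame(d1 = 1, d2 = 1,
                     fsc = 10^rnorm(5000, -2, 0.2),
                     red = 10^rnorm(5000, -1, 0.2),
                     orange = 10^rnorm(5000, -2.5, 0.2))
  members <- cluster_prochloro(pool, list())
  expect_gte(mean(members), 0.99)
})

test_that("density clusterer labels only the dominant low-scatter mode", {
  set.seed(10)
  n1 <- 5000; n2 <- 500
  pool <- data.frame(
    d1 = 1, d2 = 1,
    fsc = 10^c(rnorm(n1, -2, 0.15), rnorm(n2, 0.5, 0.15)),
    red = 10^c(rnorm(n1, -1, 0.15), rnorm(n2, 0.5, 0.15)),
    orange = 1)
  members <- cluster_prochloro(pool, list())
  expect_gte(mean(members[1:n1]), 0.99)
  expect_equal(sum(members[(n1 + 1):(n1 + n2)]), 0)
})

test_that("empty pools yield empty assignments", {
  pool <- data.frame(d1 = numeric(0), d2 = numeric(0), fsc = numeric(0),
                     red = numeric(0), orange = numeric(0))
  expect_equal(cluster_prochloro(pool, list()), logical(0))
  expect_equal(label_picoeuk(pool, c(fsc = 0, red = 0)), character(0))
})

test_that("picoeukaryote thresholds require both channels to exceed", {
  thr <- c(fsc = -1, red = -0.35)
  hi <- data.frame(d1 = 1, d2 = 1, fsc = 10^0.2, red = 10^0.5, orange = 1)
  lo_fsc <- data.frame(d1 = 1, d2 = 1, fsc = 10^-2, red = 10^0.5, orange = 1)
  expect_equal(label_picoeuk(hi, thr), "picoeuk")
  expect_equal(label_picoeuk(lo_fsc, thr), "unknown")
})

test_that("classification partitions the OPP table and is deterministic", {
  sim <- small_sim()
  fp <- small_filtration()
  ev <- sim$events[[1]]
  opp <- select_opp(ev, fp, 50)
  bead_rows <- cytocore:::gate_members(opp, sim$gating$bead_gate_raw$channels,
                                       sim$gating$bead_gate_raw$polygon)
  ref <- vapply(c("fsc", "red", "orange"),
                function(ch) median(opp[[ch]][bead_rows]), numeric(1))
  opp_n <- normalize_channels(opp, ref)
  l1 <- classify_populations(opp_n, sim$gating)
  l2 <- classify_populations(opp_n, sim$gating)
  expect_identical(l1, l2)
  expect_false(anyNA(l1))
  expect_equal(sum(table(l1)), nrow(opp))
  expect_identical(attr(l1, "gating_id"), sim$gating$gating_id)
})

test_that("gating specs round-trip through YAML with a stable id", {
  sim <- small_sim()
  p <- tempfile(fileext = ".yaml")
  write_gating_spec(sim$gating, p)
  back <- read_gating_spec(p)
  expect_identical(back$gating_id, sim$gating$gating_id)
  expect_equal(back$gates$beads$polygon, sim$gating$gates$beads$polygon)
  expect_equal(back$picoeuk_thresholds, sim$gating$picoeuk_thresholds)
})
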