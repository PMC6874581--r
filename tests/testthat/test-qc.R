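test_that("instrument thresholds are strict inequalities at the printed values", {
  meta <- data.frame(file_id = c("a", "b", "c"), cruise_id = "X",
                     stream_pressure = c(6 * 1.05, 6 * 0.95, 6),
                     event_rate = c(18000, 18001, 500),
                     stringsAsFactors = FALSE)
  # symmetric pair keeps the cruise mean at 6, so deviations are exact
  meta2 <- meta[1:2, ]
  fl <- flag_instrument(meta2)
  expect_equal(fl$flag_pressure, c(0L, 0L))  # exactly 5.0%: not "more than"
  meta2$stream_pressure <- c(6 * 1.051, 6 * 0.949)
  expect_equal(flag_instrument(meta2)$flag_pressure, c(1L, 1L))
  fl3 <- flag_instrument(meta)
  expect_equal(fl3$flag_rate, c(0L, 1L, 0L))  # 18000 passes, 18001 fails
})

test_that("instrument flags match a per-file scalar oracle and ignore order", {
  set.seed(13)
  n <- 1000
  meta <- data.frame(
    file_id = sprintf("f%04d", 1:n),
    cruise_id = sample(c("A", "B", "C"), n, replace = TRUE),
    stream_pressure = rnorm(n, 6, 0.4),
    event_rate = runif(n, 0, 30000),
    stringsAsFactors = FALSE)
  meta$stream_pressure[sample(n, 20)] <- NA
  fl <- flag_instrument(meta)
  for (i in sample(n, 200)) {
    p <- meta$stream_pressure[i]
    if (!is.finite(p)) {
      expect_true(is.na(fl$flag_pressure[i]))
    } else {
      cruise_p <- meta$stream_pressure[meta$cruise_id == meta$cruise_id[i]]
      m <- mean(cruise_p, na.rm = TRUE)
      expect_identical(fl$flag_pressure[i], as.integer(abs(p - m) / m > 0.05))
    }
    expect_identical(fl$flag_rate[i], as.integer(meta$event_rate[i] > 18000))
  }
  perm <- sample(n)
  fl_perm <- flag_instrument(meta[perm, ])
  expect_identical(fl_perm[order(match(fl_perm$file_id, meta$file_id)), "flag_pressure"],
                   fl$flag_pressure)
})

test_that("all-missing pressures give not-evaluable flags", {
  meta <- data.frame(file_id = c("a", "b"), cruise_id = "X",
                     stream_pressure = NA_real_, event_rate = NA_real_)
  fl <- flag_instrument(meta)
  expect_true(all(is.na(fl$flag_pressure)))
  expect_true(all(is.na(fl$flag_rate)))
})

test_that("Chauvenet flags the textbook outlier and tolerates degeneracy", {
  mask <- chauvenet(c(1, 1, 1, 1, 100))
  expect_identical(mask, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # direct evaluation of the tail: z ~ 1.79 so N * P ~ 0.37 < 0.5
  z <- abs(100 - mean(c(1, 1, 1, 1, 100))) / sd(c(1, 1, 1, 1, 100))
  expect_lt(5 * 2 * pnorm(z, lower.tail = FALSE), 0.5)
  expect_identical(chauvenet(rep(0, 5)), rep(FALSE, 5))
  expect_error(chauvenet(c(1, 2, 3)), "N >= 4")
  expect_error(chauvenet(c(1, 2, 3, NA)), "finite")
})

test_that("the Chauvenet mask is location-scale free", {
  set.seed(17)
  for (rep in 1:20) {
    v <- rnorm(50, 10, 3)
    m <- chauvenet(v)
    expect_identical(chauvenet(7 - 3.2 * v), m)
    expect_identical(chauvenet(v * 1e6 + 5), m)
  }
})

test_that("clean normal samples are rarely flagged", {
  set.seed(19)
  frac <- replicate(30, mean(chauvenet(rnorm(1000))))
  expect_lt(mean(frac), 0.01)
})

test_that("qc_screen attaches tri-state flags per cruise and population", {
  rec <- expand.grid(cruise = "X", population = c("prochloro", "synecho"),
                     file_id = sprintf("f%02d", 1:6), stringsAsFactors = FALSE)
  set.seed(23)
  rec$abundance <- rnorm(nrow(rec), 100, 1)
  rec$abundance[1] <- 500  # gross outlier in prochloro
  rec$esd_n138_med <- rnorm(nrow(rec), 1, 0.01)
  rec$carbon_n138_med <- NA_real_
  out <- qc_screen(rec)
  expect_identical(out$flag_abundance[1], 1L)
  expect_true(all(out$flag_abundance[-1] == 0L))
  expect_true(all(is.na(out$flag_carbon)))  # not evaluable on missing values
})
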