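# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small Mie model (coarse grid) for fast unit tests
small_mie <- function() fixture("small_mie", function() mie_model(grid_n = 400))

# scaled-down simulated cruise: short files keep unit tests quick while
# preserving the full statistical structure
small_sim <- function() fixture("small_sim", function() {
  simulate_cruise(sim_config(seed = 42, n_files = 2, duration = 30,
                             mie = list(grid_n = 400)))
})

# the same cruise written to disk, for pipeline tests
small_sim_dir <- function() fixture("small_sim_dir", function() {
  d <- file.path(tempdir(), "cytocore-small-sim")
  simulate_cruise(sim_config(seed = 42, n_files = 2, duration = 30,
                             mie = list(grid_n = 400)), dir = d)
  d
})

small_pipeline_config <- function(out = tempfile("out")) {
  d <- small_sim_dir()
  list(input_dir = file.path(d, "events"),
       metadata = file.path(d, "metadata.csv"),
       bead_table = file.path(d, "beads.csv"),
       gating_spec = file.path(d, "gating.yaml"),
       output_dir = out,
       mie = list(grid_n = 400))
}

# random but valid event table
random_events <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(d1 = rlnorm(n, 2), d2 = rlnorm(n, 2), fsc = rlnorm(n, 3),
             red = rlnorm(n, 1), orange = rlnorm(n, 1))
}

# fitted filtration params from the small simulated cruise
small_filtration <- function() fixture("small_filtration", function() {
  sim <- small_sim()
  ev <- do.call(rbind, sim$events)
  mask <- cytocore:::gate_members(ev, sim$gating$bead_gate_raw$channels,
                                  sim$gating$bead_gate_raw$polygon)
  fit_filtration_params(ev, mask)
})

# independent ray-casting point-in-polygon oracle (even-odd rule)
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# random simple (star-shaped) polygon around a center
random_star_polygon <- function(k = 6, center = c(0, 0), rmin = 0.5, rmax = 2) {
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, rmin, rmax)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# brute-force pinball (quantile regression) loss for a slope through the
# anchor, used as an oracle for the anchored fits
pinball_loss <- function(b, x, y, tau) {
  r <- y - b * x
  sum(r * (tau - (r < 0)))
}
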