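# Ground-truthed cruise simulator: Poisson particle arrivals, Mie-derived
# forward scatter, a radially symmetric virtual-core acceptance model for
# the position detectors, lognormal pigment fluorescence, injected beads,
# and matched gating specifications.

#' Default simulated population parameters
#'
#' Concentrations, lognormal size distributions and pigment signatures for
#' the four picophytoplankton populations, chosen to resemble oligotrophic
#' subtropical surface waters: abundant dim \emph{Prochlorococcus} (~0.6
#' micron), sparser phycoerythrin-rich \emph{Synechococcus} (~1.1 micron),
#' rare large \emph{Crocosphaera} (~3 micron) and mid-abundance
#' picoeukaryotes (~2 micron) with bright chlorophyll fluorescence.
#' Fluorescence means/sds are in log10 bead-normalized units; population
#' centroids are at least one decade apart in their gating planes.
#'
#' @param preset \code{"default"} (separable populations) or \code{"hard"}
#'   (\emph{Prochlorococcus} pushed toward the noise floor with a wider,
#'   dimmer signature, to exercise the density clusterer).
#' @return Data frame with one row per population.
#' @export
default_populations <- function(preset = c("default", "hard")) {
  preset <- match.arg(preset)
  df <- data.frame(
    population   = c("prochloro", "synecho", "croco", "picoeuk"),
    concentration = c(200, 20, 2, 10),          # cells per microliter
    diam_geomean = c(0.6, 1.1, 3.0, 2.0),       # micron
    diam_sdlog10 = c(0.05, 0.05, 0.05, 0.08),
    n_index      = c(1.38, 1.38, 1.38, 1.38),
    red_mean     = c(-1.2, -0.5, -0.2, 0.5),    # log10 bead-normalized
    red_sd       = c(0.15, 0.15, 0.15, 0.15),
    orange_mean  = c(-2.5, -1.0, 1.0, -2.0),
    orange_sd    = c(0.15, 0.15, 0.15, 0.20),
    stringsAsFactors = FALSE)
  if (preset == "hard") {
    i <- df$population == "prochloro"
    df$diam_geomean[i] <- 0.5
    df$diam_sdlog10[i] <- 0.10
    df$red_mean[i] <- -1.6
    df$red_sd[i] <- 0.25
  }
  df
}

#' Simulation configuration
#'
#' Bundles every knob of the cruise simulator. The acceptance physics of
#' the virtual core is modeled as a radially symmetric gain on the two
#' position detectors with opposing lateral sensitivity: a particle at
#' radial position r (stream radius 1) and lateral offset u contributes
#' \code{d = fsc * gain_center * exp((r/gain_width)^2) * exp(+/- lateral_sensitivity * u)}
#' times multiplicative lognormal noise, so centered particles give equal,
#' low position-detector signals relative to forward scatter.
#'
#' @param seed integer seed fixing the full stream.
#' @param n_files number of three-minute acquisition files.
#' @param duration acquisition duration per file, seconds.
#' @param flow_rate sample-stream flow rate, mL/min.
#' @param flow_rate_se_frac relative flow-rate calibration SE.
#' @param populations population table (see \code{\link{default_populations}}).
#' @param bead list: \code{concentration} (beads/uL), \code{diameter}
#'   (micron, the primary 1-micron normalization bead), \code{n}
#'   (refractive index), \code{ladder} (additional bead diameters co-run
#'   for calibration, spanning the scatter range so the anchored
#'   filtration regressions are well conditioned) and
#'   \code{ladder_fraction} (fraction of bead concentration spread evenly
#'   over the ladder).
#' @param core virtual-core acceptance model: \code{gain_center},
#'   \code{gain_width}, \code{lateral_sensitivity},
#'   \code{core_radius_fraction} (radius fraction used by recovery checks).
#' @param noise multiplicative measurement noise, sd in log10 units:
#'   \code{common} is the per-particle illumination/stream fluctuation
#'   shared by forward scatter and both position detectors (the same laser
#'   interaction feeds all three), \code{fsc} and \code{d} are the smaller
#'   detector-specific terms.
#' @param gains raw instrument gain per channel (converts bead-normalized
#'   to instrument units).
#' @param mie forward-model settings passed to \code{\link{mie_model}}.
#' @param bead_table_noise log10 noise sd on the emitted bead calibration
#'   table (the 1-micron row is renormalized to exactly 1).
#' @param qc_faults optional list: \code{pressure_files}, \code{pressure_dev}
#'   (fractional deviation), \code{rate_files}, \code{rate_value}.
#' @param cruise_id,start_time,start_lat,start_lon cruise metadata.
#' @param dialect event-file dialect for \code{\link{simulate_cruise}}.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_files = 10L, duration = 180,
                       flow_rate = 0.1, flow_rate_se_frac = 0.05,
                       populations = default_populations(),
                       bead = list(concentration = 1, diameter = 1.0, n = 1.60,
                                   ladder = c(0.3, 0.5, 0.75, 1.83, 3.1, 5.7),
                                   ladder_fraction = 0.4),
                       core = list(gain_center = 0.3, gain_width = 1.0,
                                   lateral_sensitivity = 0.5,
                                   core_radius_fraction = 0.25),
                       noise = list(common = 0.04, fsc = 0.02, d = 0.02),
                       gains = list(fsc = 1000, red = 500, orange = 400),
                       mie = list(),
                       bead_table_noise = 0.01,
                       qc_faults = NULL,
                       cruise_id = "SIMCRUISE",
                       start_time = as.POSIXct("2017-06-15 00:00:00", tz = "UTC"),
                       start_lat = 22.75, start_lon = -158,
                       dialect = "csv") {
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == round(seed)),
            is_count(as.numeric(n_files)), n_files >= 1,
            duration > 0, flow_rate > 0, flow_rate_se_frac >= 0,
            all(populations$concentration >= 0),
            all(populations$diam_sdlog10 >= 0),
            all(populations$red_sd > 0), all(populations$orange_sd > 0),
            bead$concentration >= 0, bead$diameter > 0,
            core$gain_center > 0, core$gain_width > 0,
            core$core_radius_fraction > 0, core$core_radius_fraction < 1,
            noise$common > 0, noise$fsc > 0, noise$d > 0)
  structure(list(seed = as.integer(seed), n_files = as.integer(n_files),
                 duration = duration, flow_rate = flow_rate,
                 flow_rate_se_frac = flow_rate_se_frac,
                 populations = populations, bead = bead, core = core,
                 noise = noise, gains = gains, mie = mie,
                 bead_table_noise = bead_table_noise,
                 qc_faults = qc_faults, cruise_id = cruise_id,
                 start_time = start_time, start_lat = start_lat,
                 start_lon = start_lon, dialect = dialect),
            class = "sim_config")
}

# log10 response curve and local log-log slope for one refractive index.
sim_response_curve <- function(model, n_index) {
  raw <- detector_response(model$diameter_grid, n_index, model)
  ld <- log10(model$diameter_grid)
  lr <- log10(raw)
  list(fun = approxfun(ld, lr, rule = 2),
       slope = approxfun(ld[-1] - diff(ld) / 2, diff(lr) / diff(ld), rule = 2))
}

# Matched gating spec derived from the configuration and forward model.
sim_gating_spec <- function(config, curves) {
  pops <- config$populations
  centers <- lapply(seq_len(nrow(pops)), function(i) {
    cv <- curves[[as.character(pops$n_index[i])]]
    ld <- log10(pops$diam_geomean[i])
    lfsc <- cv$fun(ld)
    sd_lfsc <- sqrt((cv$slope(ld) * pops$diam_sdlog10[i])^2 +
                      config$noise$common^2 + config$noise$fsc^2)
    list(fsc = lfsc, fsc_sd = sd_lfsc,
         red = pops$red_mean[i], red_sd = pops$red_sd[i],
         orange = pops$orange_mean[i], orange_sd = pops$orange_sd[i])
  })
  names(centers) <- pops$population
  box <- function(cx, cy, hx, hy) {
    matrix(c(cx - hx, cy - hy, cx + hx, cy - hy,
             cx + hx, cy + hy, cx - hx, cy + hy),
           ncol = 2, byrow = TRUE)
  }
  hw <- function(s) max(0.35, 3.5 * s)
  # the bead gate must span the whole bead diameter ladder in scatter
  bead_lfsc <- curves[[as.character(config$bead$n)]]$fun(
    log10(c(config$bead$diameter, config$bead$ladder %||% numeric(0))))
  bead_fsc_c <- mean(range(bead_lfsc))
  bead_hw_fsc <- diff(range(bead_lfsc)) / 2 +
    hw(sqrt(config$noise$common^2 + config$noise$fsc^2))
  gates <- list(
    beads = list(channels = c("fsc", "orange"),
                 polygon = box(bead_fsc_c, 0, bead_hw_fsc, 0.35)),
    synecho = list(channels = c("orange", "red"),
                   polygon = box(centers$synecho$orange, centers$synecho$red,
                                 hw(centers$synecho$orange_sd),
                                 hw(centers$synecho$red_sd))),
    croco = list(channels = c("fsc", "orange"),
                 polygon = box(centers$croco$fsc, centers$croco$orange,
                               hw(centers$croco$fsc_sd),
                               hw(centers$croco$orange_sd))))
  thresholds <- c(fsc = (centers$prochloro$fsc + centers$picoeuk$fsc) / 2,
                  red = (centers$prochloro$red + centers$picoeuk$red) / 2)
  # beads are flagged pre-normalization by their fluorescence signature,
  # which is shared across the ladder diameters
  bead_gate_raw <- list(channels = c("orange", "red"),
                        polygon = box(log10(config$gains$orange),
                                      log10(config$gains$red),
                                      0.35, 0.35))
  gating_spec(gates, cluster_params = list(), picoeuk_thresholds = thresholds,
              bead_gate_raw = bead_gate_raw)
}

#' Simulate a ground-truthed cruise
#'
#' Generates event tables, per-file metadata, a bead calibration table, a
#' matched gating specification and the simulation truth. Particle counts
#' per population and file are Poisson with rate concentration x flow;
#' each particle draws a lognormal diameter and a uniform position in the
#' stream cross-section; forward scatter comes from the Mie forward model
#' (multiplicative lognormal noise), the position-detector signals from
#' the radial gain model, and fluorescence from per-population lognormal
#' signatures. Calibration beads are injected at their fixed diameter.
#' Everything is deterministic given the seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir optional directory; when given, event files, metadata, bead
#'   table, gating spec and per-file truth are written there.
#' @return Invisibly, a list with \code{events} (named list of event
#'   tables), \code{metadata}, \code{beads}, \code{gating},
#'   \code{truth} (list \code{particles}, \code{files}), \code{model} and
#'   \code{config}.
#' @export
simulate_cruise <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- do.call(mie_model, config$mie)
  pops <- config$populations
  indices <- unique(c(pops$n_index, config$bead$n))
  curves <- lapply(indices, function(n) sim_response_curve(model, n))
  names(curves) <- as.character(indices)

  # emitted bead calibration table (standard bead diameter ladder)
  bead_d <- c(0.3, 0.5, 0.75, 1, 1.83, 3.1, 5.7)
  meas <- 10^(curves[[as.character(config$bead$n)]]$fun(log10(bead_d)) +
                rnorm(length(bead_d), 0, config$bead_table_noise))
  meas <- meas / meas[bead_d == 1]
  beads_tbl <- bead_table(bead_d, config$bead$n, meas)

  gating <- sim_gating_spec(config, curves)

  flow_uls <- config$flow_rate * 1000 / 60
  all_pop <- rbind(
    pops[c("population", "concentration", "diam_geomean", "diam_sdlog10",
           "n_index", "red_mean", "red_sd", "orange_mean", "orange_sd")],
    data.frame(population = "beads", concentration = config$bead$concentration,
               diam_geomean = config$bead$diameter, diam_sdlog10 = 0,
               n_index = config$bead$n, red_mean = 0, red_sd = 0.05,
               orange_mean = 0, orange_sd = 0.05, stringsAsFactors = FALSE))
  grng <- range(model$diameter_grid)

  events <- list()
  truth_particles <- list()
  meta_rows <- list()
  for (f in seq_len(config$n_files)) {
    file_id <- sprintf("%s_%04d", config$cruise_id, f)
    parts <- list()
    for (i in seq_len(nrow(all_pop))) {
      n_i <- rpois(1, all_pop$concentration[i] * flow_uls * config$duration)
      if (n_i == 0) next
      if (all_pop$population[i] == "beads" && length(config$bead$ladder %||% numeric(0))) {
        lf <- config$bead$ladder_fraction %||% 0.4
        sizes <- c(config$bead$diameter, config$bead$ladder)
        probs <- c(1 - lf, rep(lf / length(config$bead$ladder),
                               length(config$bead$ladder)))
        d <- sample(sizes, n_i, replace = TRUE, prob = probs)
      } else {
        d <- rlnorm(n_i, log(all_pop$diam_geomean[i]),
                    all_pop$diam_sdlog10[i] * log(10))
      }
      d <- pmin(pmax(d, grng[1] * 1.02), grng[2] * 0.98)
      r <- sqrt(runif(n_i))
      u <- r * cos(runif(n_i, 0, 2 * pi))
      lresp <- curves[[as.character(all_pop$n_index[i])]]$fun(log10(d))
      fsc_true <- 10^lresp
      gain <- config$core$gain_center * exp((r / config$core$gain_width)^2)
      lat_gain <- config$core$lateral_sensitivity * u
      common <- 10^rnorm(n_i, 0, config$noise$common)
      d1 <- fsc_true * common * gain * exp(lat_gain) * 10^rnorm(n_i, 0, config$noise$d)
      d2 <- fsc_true * common * gain * exp(-lat_gain) * 10^rnorm(n_i, 0, config$noise$d)
      fsc <- fsc_true * common * 10^rnorm(n_i, 0, config$noise$fsc)
      red <- 10^rnorm(n_i, all_pop$red_mean[i], all_pop$red_sd[i])
      orange <- 10^rnorm(n_i, all_pop$orange_mean[i], all_pop$orange_sd[i])
      parts[[i]] <- data.frame(
        population = all_pop$population[i], diameter = d, r = r, u = u,
        d1 = d1 * config$gains$fsc, d2 = d2 * config$gains$fsc,
        fsc = fsc * config$gains$fsc, red = red * config$gains$red,
        orange = orange * config$gains$orange, stringsAsFactors = FALSE)
    }
    allp <- do.call(rbind, parts)
    ord <- sample.int(nrow(allp))
    allp <- allp[ord, , drop = FALSE]
    ev <- validate_events(allp[c("d1", "d2", "fsc", "red", "orange")], file_id)
    events[[file_id]] <- ev
    truth_particles[[file_id]] <- data.frame(
      file_id = file_id, allp[c("population", "diameter", "r", "u")],
      row.names = NULL, stringsAsFactors = FALSE)
    meta_rows[[f]] <- data.frame(
      file_id = file_id, cruise_id = config$cruise_id,
      timestamp = config$start_time + (f - 1) * config$duration,
      lat = config$start_lat + 0.01 * (f - 1),
      lon = config$start_lon + 0.01 * (f - 1),
      duration = config$duration,
      flow_rate = config$flow_rate,
      flow_rate_se = config$flow_rate_se_frac * config$flow_rate,
      stream_pressure = 6 + rnorm(1, 0, 0.02),
      event_rate = nrow(ev) / config$duration,
      sst = 25 + rnorm(1, 0, 0.1),
      salinity = 35 + rnorm(1, 0, 0.02),
      par = round(pmax(0, 1500 * sin(pi * (((f - 1) * config$duration / 3600) %% 24) / 12)), 3),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_rows)
  if (!is.null(config$qc_faults)) {
    qf <- config$qc_faults
    if (length(qf$pressure_files)) {
      i <- match(qf$pressure_files, seq_len(nrow(meta)))
      meta$stream_pressure[i] <- meta$stream_pressure[i] * (1 + (qf$pressure_dev %||% 0.2))
    }
    if (length(qf$rate_files))
      meta$event_rate[qf$rate_files] <- qf$rate_value %||% 25000
  }
  truth_files <- merge(
    data.frame(file_id = meta$file_id, stringsAsFactors = FALSE),
    setNames(all_pop[c("population", "concentration")],
             c("population", "true_concentration")))
  truth <- list(particles = do.call(rbind, c(truth_particles, list(make.row.names = FALSE))),
                files = truth_files[order(truth_files$file_id, truth_files$population), ])

  out <- list(events = events, metadata = meta, beads = beads_tbl,
              gating = gating, truth = truth, model = model, config = config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
    ext <- if (config$dialect == "csv") "csv" else "bin"
    for (fid in names(events))
      write_events(events[[fid]], file.path(dir, "events", paste0(fid, ".", ext)),
                   dialect = config$dialect)
    write_metadata(meta, file.path(dir, "metadata.csv"))
    write_bead_table(beads_tbl, file.path(dir, "beads.csv"))
    write_gating_spec(gating, file.path(dir, "gating.yaml"))
    write.csv(truth$files, file.path(dir, "truth_files.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
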