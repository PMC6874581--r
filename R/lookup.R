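# Monotone scatter-to-diameter lookup tables and the biovolume-to-carbon
# power law.

#' Build a monotone scatter lookup table
#'
#' Evaluates the calibrated detector response over the model's diameter grid
#' for one refractive index, then replaces the (mildly oscillating) Mie
#' curve with its least-squares monotone non-decreasing fit
#' (\code{\link[stats]{isoreg}}) so that inversion from scatter to diameter
#' is single-valued. Within flat stretches of the monotone fit, inversion
#' ties are broken toward the smaller diameter.
#'
#' @param model a \code{\link{mie_model}}, normally after
#'   \code{\link{calibrate_geometry}}.
#' @param n_particle refractive index for which to build the table.
#' @param nodes quadrature nodes per diameter.
#' @return An object of class \code{scatter_lookup} with the diameter grid,
#'   raw and monotone responses.
#' @export
build_lookup <- function(model, n_particle, nodes = 48) {
  stopifnot(inherits(model, "mie_model"))
  d <- model$diameter_grid
  raw <- detector_response(d, n_particle, model, nodes)
  iso <- isoreg(seq_along(d), raw)$yf
  structure(list(
    diameter = d,
    response_raw = raw,
    response = iso,
    n_particle = n_particle,
    wavelength = model$wavelength,
    n_medium = model$n_medium,
    inner = model$inner,
    outer = model$outer
  ), class = "scatter_lookup")
}

#' @export
print.scatter_lookup <- function(x, ...) {
  cat(sprintf(
    "Scatter lookup: n = %.3f, %d grid points on [%.2f, %.2f] micron,\n  normalized response range [%.3g, %.3g]\n",
    x$n_particle, length(x$diameter), min(x$diameter), max(x$diameter),
    min(x$response), max(x$response)))
  invisible(x)
}

#' Invert bead-normalized scatter to equivalent spherical diameter
#'
#' Linear interpolation in (log10 scatter, log10 diameter) on the monotone
#' lookup. Scatter outside the table range is clamped to the corresponding
#' endpoint diameter and flagged; non-positive scatter yields \code{NA}
#' with its own flag.
#'
#' @param norm_scatter bead-normalized forward scatter values.
#' @param lookup a \code{\link{build_lookup}} table.
#' @return A data frame with columns \code{esd} (micron) and \code{flag}
#'   (\code{"ok"}, \code{"clamped_low"}, \code{"clamped_high"},
#'   \code{"nonpositive"}).
#' @export
scatter_to_esd <- function(norm_scatter, lookup) {
  stopifnot(inherits(lookup, "scatter_lookup"))
  # collapse flat stretches: first (smallest-diameter) point of each run
  keep <- !duplicated(lookup$response)
  lr <- log10(lookup$response[keep])
  ld <- log10(lookup$diameter[keep])
  esd <- rep(NA_real_, length(norm_scatter))
  flag <- rep("nonpositive", length(norm_scatter))
  pos <- is.finite(norm_scatter) & norm_scatter > 0
  if (any(pos)) {
    ls <- log10(norm_scatter[pos])
    f <- rep("ok", sum(pos))
    f[ls < lr[1]] <- "clamped_low"
    f[ls > lr[length(lr)]] <- "clamped_high"
    if (length(lr) >= 2) {
      v <- approx(lr, ld, xout = ls, rule = 2, ties = "ordered")$y
    } else {
      v <- rep(ld[1], sum(pos))
    }
    esd[pos] <- 10^v
    flag[pos] <- f
  }
  data.frame(esd = esd, flag = flag, stringsAsFactors = FALSE)
}

#' Carbon conversion parameters
#'
#' The power law converting cell biovolume to cellular carbon,
#' \code{fgC = a * volume^b} with defaults a = 0.261 and b = 0.860 for
#' volume in cubic micron.
#'
#' @param a coefficient (fgC per cell at 1 cubic micron), > 0.
#' @param b exponent, in (0, 1].
#' @export
carbon_params <- function(a = 0.261, b = 0.860) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, b > 0, b <= 1)
  structure(list(a = a, b = b), class = "carbon_params")
}

#' Cellular carbon from biovolume
#'
#' @param volume cell volume(s) in cubic micron (\code{(pi/6) * ESD^3} for
#'   spheres); must be non-negative.
#' @param params a \code{\link{carbon_params}} object.
#' @return Carbon quota in fgC per cell.
#' @examples
#' carbon_from_volume(1)            # 0.261 fgC
#' carbon_from_volume(pi / 6 * 2^3) # a 2-micron sphere
#' @export
carbon_from_volume <- function(volume, params = carbon_params()) {
  stopifnot(inherits(params, "carbon_params"))
  if (any(!is.finite(volume)) || any(volume < 0))
    stop_cyto("volume must be finite and non-negative")
  params$a * volume^params$b
}

#' ESD to spherical biovolume
#'
#' @param esd equivalent spherical diameter in micron.
#' @return Volume in cubic micron, \code{(pi/6) esd^3}.
#' @export
esd_to_volume <- function(esd) (pi / 6) * esd^3
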