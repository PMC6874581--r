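# Mie scattering forward model for homogeneous spheres and the detector
# geometry used to convert bead-normalized forward scatter to cell size.

# Series truncation after Wiscombe: N = ceil(x + 4 x^(1/3) + 2).
mie_nstop <- function(x) as.integer(ceiling(x + 4 * x^(1 / 3) + 2))

# Mie coefficients a_n, b_n (n = 1..N) for relative refractive index m and
# size parameter x. Logarithmic derivative by downward recurrence, the
# Riccati-Bessel functions psi/chi by upward recurrence (stable up to the
# truncation order used here).
mie_ab <- function(m, x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_cyto("size parameter x must be a positive finite number (got %s)", format(x))
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop_cyto("relative refractive index m must be positive and finite")
  N <- mie_nstop(x)
  mx <- m * x
  nmx <- max(N, ceiling(abs(mx))) + 16L
  Dvec <- numeric(N)
  Dn <- 0
  for (n in nmx:1) {
    Dprev <- n / mx - 1 / (Dn + n / mx)
    if (n - 1L >= 1L && n - 1L <= N) Dvec[n - 1L] <- Dprev
    Dn <- Dprev
  }
  nn <- seq_len(N)
  psi <- numeric(N); chi <- numeric(N)
  psi_m2 <- cos(x); psi_m1 <- sin(x)     # psi_{-1}, psi_0
  chi_m2 <- -sin(x); chi_m1 <- cos(x)    # chi_{-1}, chi_0
  for (n in nn) {
    psi[n] <- (2 * n - 1) / x * psi_m1 - psi_m2
    chi[n] <- (2 * n - 1) / x * chi_m1 - chi_m2
    psi_m2 <- psi_m1; psi_m1 <- psi[n]
    chi_m2 <- chi_m1; chi_m1 <- chi[n]
  }
  psi_prev <- c(sin(x), psi[-N])
  chi_prev <- c(cos(x), chi[-N])
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  fa <- Dvec / m + nn / x
  fb <- Dvec * m + nn / x
  a <- (fa * psi - psi_prev) / (fa * xi - xi_prev)
  b <- (fb * psi - psi_prev) / (fb * xi - xi_prev)
  list(n = nn, a = a, b = b)
}

# Angular functions pi_n(mu), tau_n(mu) for n = 1..N, as N x length(mu)
# matrices (standard three-term recurrences).
mie_angular <- function(mu, N) {
  nmu <- length(mu)
  P <- matrix(0, N, nmu)
  Tau <- matrix(0, N, nmu)
  pi_m1 <- rep(0, nmu)   # pi_0
  pi_n <- rep(1, nmu)    # pi_1
  for (k in seq_len(N)) {
    Tau[k, ] <- k * mu * pi_n - (k + 1) * pi_m1
    P[k, ] <- pi_n
    pi_next <- ((2 * k + 1) * mu * pi_n - (k + 1) * pi_m1) / k
    pi_m1 <- pi_n
    pi_n <- pi_next
  }
  list(pi = P, tau = Tau)
}

#' Mie scattering efficiency and phase function of a homogeneous sphere
#'
#' Computes the scattering efficiency Qsca and, optionally, the complex
#' scattering amplitudes and unpolarized phase intensity at the requested
#' scattering angles, from the Mie coefficient series truncated at
#' \code{N = ceiling(x + 4 x^(1/3) + 2)}.
#'
#' @param m real relative refractive index (particle over medium).
#' @param x size parameter \code{pi * D * n_medium / lambda} (dimensionless,
#'   > 0).
#' @param theta optional scattering angles in radians at which to evaluate
#'   the phase function.
#' @return A list with \code{qsca}, \code{n_terms}, and — when \code{theta}
#'   is supplied — \code{s1}, \code{s2} (complex amplitudes) and
#'   \code{intensity}, the unpolarized intensity
#'   \code{(|S1|^2 + |S2|^2) / 2}.
#' @examples
#' mie_scattering(1.5, 1)$qsca
#' mie_scattering(1.38 / 1.34, 5, theta = pi / 18)$intensity
#' @export
mie_scattering <- function(m, x, theta = NULL) {
  ab <- mie_ab(m, x)
  nn <- ab$n
  qsca <- (2 / x^2) * sum((2 * nn + 1) * (Mod(ab$a)^2 + Mod(ab$b)^2))
  out <- list(qsca = qsca, n_terms = length(nn))
  if (!is.null(theta)) {
    ang <- mie_angular(cos(theta), length(nn))
    f <- (2 * nn + 1) / (nn * (nn + 1))
    s1 <- as.vector(t(ang$pi) %*% (f * ab$a) + t(ang$tau) %*% (f * ab$b))
    s2 <- as.vector(t(ang$tau) %*% (f * ab$a) + t(ang$pi) %*% (f * ab$b))
    out$s1 <- s1
    out$s2 <- s2
    out$intensity <- 0.5 * (Mod(s1)^2 + Mod(s2)^2)
  }
  out
}

#' Construct a Mie detector model
#'
#' Bundles the optical constants and forward-detector acceptance geometry
#' used to predict bead-normalized forward scatter of homogeneous spheres.
#' The detector is modeled as an annular cone seen from the interrogation
#' point, bounded by two half-angles; light scattered into that annulus is
#' integrated and divided by the same quantity for a 1-micron sphere of the
#' bead refractive index, so a 1-micron bead has response exactly 1.
#'
#' @param wavelength laser wavelength in nm (default 457, the center of the
#'   forward-scatter bandpass).
#' @param n_medium refractive index of seawater (default 1.34).
#' @param n_cells refractive indices used for phytoplankton cells.
#' @param n_bead refractive index of the calibration beads.
#' @param inner,outer half-angles (degrees) of the acceptance annulus,
#'   0 < inner < outer < 90.
#' @param grid_n,grid_range size and range (micron) of the log-spaced
#'   diameter grid used for lookup tables.
#' @return An object of class \code{mie_model}.
#' @examples
#' m <- mie_model()
#' detector_response(1, 1.60, m)  # exactly 1 by bead normalization
#' @export
mie_model <- function(wavelength = 457, n_medium = 1.34,
                      n_cells = c(1.35, 1.38, 1.41), n_bead = 1.60,
                      inner = 2, outer = 15,
                      grid_n = 2000, grid_range = c(0.2, 6.0)) {
  stopifnot(wavelength > 0, n_medium > 1, all(n_cells > n_medium - 0.1),
            grid_n >= 10, grid_range[1] > 0, grid_range[2] > grid_range[1])
  if (!(inner > 0 && inner < outer && outer < 90))
    stop_cyto("acceptance geometry requires 0 < inner < outer < 90 degrees")
  structure(list(
    wavelength = wavelength,
    n_medium = n_medium,
    n_cells = sort(n_cells),
    n_bead = n_bead,
    inner = inner,
    outer = outer,
    diameter_grid = exp(seq(log(grid_range[1]), log(grid_range[2]),
                            length.out = grid_n)),
    calibration = NULL
  ), class = "mie_model")
}

#' @export
print.mie_model <- function(x, ...) {
  cat("Mie detector model\n")
  cat(sprintf("  wavelength: %g nm, medium index %.3f, bead index %.3f\n",
              x$wavelength, x$n_medium, x$n_bead))
  cat(sprintf("  cell indices: %s\n", paste(x$n_cells, collapse = ", ")))
  cat(sprintf("  acceptance annulus: %.3f - %.3f degrees%s\n", x$inner, x$outer,
              if (is.null(x$calibration)) " (uncalibrated)" else ""))
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated on %d beads, R^2 = %.5f\n",
                x$calibration$n_beads, x$calibration$r_squared))
  cat(sprintf("  diameter grid: %d points on [%.2f, %.2f] micron\n",
              length(x$diameter_grid), min(x$diameter_grid), max(x$diameter_grid)))
  invisible(x)
}

size_parameter <- function(diameter_um, model) {
  pi * diameter_um * model$n_medium / (model$wavelength / 1000)
}

# Raw (unnormalized) detector integral for one diameter: integral of the
# unpolarized phase intensity over the acceptance annulus, Gauss-Legendre
# quadrature in scattering angle.
detector_integral <- function(diameter, n_particle, model, nodes = 48) {
  gl <- pracma::gaussLegendre(nodes, model$inner * pi / 180, model$outer * pi / 180)
  x <- size_parameter(diameter, model)
  m <- n_particle / model$n_medium
  out <- numeric(length(diameter))
  for (i in seq_along(diameter)) {
    sc <- mie_scattering(m, x[i], theta = gl$x)
    out[i] <- sum(gl$w * sc$intensity * sin(gl$x))
  }
  out
}

#' Predicted bead-normalized detector response
#'
#' Forward scatter predicted for a homogeneous sphere, expressed in
#' bead-normalized units: the acceptance-annulus integral of the unpolarized
#' Mie phase intensity, divided by the same integral for a 1-micron sphere
#' of the bead refractive index.
#'
#' @param diameter sphere diameter(s) in micron; must lie within the model's
#'   diameter grid range.
#' @param n_particle particle refractive index.
#' @param model a \code{\link{mie_model}}.
#' @param nodes number of quadrature nodes across the annulus.
#' @return Numeric vector of normalized responses.
#' @export
detector_response <- function(diameter, n_particle, model, nodes = 48) {
  rng <- range(model$diameter_grid)
  bad <- diameter < rng[1] - 1e-9 | diameter > rng[2] + 1e-9
  if (any(bad))
    stop_cyto("diameter %s micron outside the model grid range [%g, %g]",
              format(diameter[bad][1]), rng[1], rng[2])
  detector_integral(diameter, n_particle, model, nodes) /
    detector_integral(1.0, model$n_bead, model, nodes)
}

#' Calibrate detector acceptance geometry against beads
#'
#' Fits the two half-angles of the acceptance annulus by minimizing the sum
#' of squared log10 residuals between predicted and measured bead-normalized
#' scatter of calibration beads. Several starting geometries (the model's
#' current one plus fixed alternates) are tried with Nelder-Mead; the best
#' fit wins. If no start improves on the current geometry, a warning is
#' issued and the model is returned unchanged apart from the fit report.
#'
#' @param beads a bead calibration table from \code{\link{bead_table}} (or a
#'   data frame with columns \code{diameter}, \code{refractive_index},
#'   \code{measured_norm_scatter}); at least 3 rows spanning at least one
#'   decade of diameter.
#' @param model a \code{\link{mie_model}}.
#' @param nodes quadrature nodes used during fitting.
#' @return The model with updated \code{inner}/\code{outer} and a
#'   \code{calibration} element holding the angles, R-squared of the log-log
#'   fit, and convergence information.
#' @export
calibrate_geometry <- function(beads, model, nodes = 48) {
  beads <- validate_bead_table(beads)
  if (nrow(beads) < 3)
    stop_cyto("bead calibration needs at least 3 rows, got %d", nrow(beads))
  if (log10(max(beads$diameter) / min(beads$diameter)) < 1)
    stop_cyto("bead diameters must span at least one decade")
  ly <- log10(beads$measured_norm_scatter)
  ss_for <- function(inner, outer) {
    m2 <- model
    m2$inner <- inner; m2$outer <- outer
    pred <- vapply(seq_len(nrow(beads)), function(i)
      detector_response(beads$diameter[i], beads$refractive_index[i], m2, nodes),
      numeric(1))
    if (any(pred <= 0) || any(!is.finite(pred))) return(Inf)
    sum((log10(pred) - ly)^2)
  }
  obj <- function(p) {
    inner <- exp(p[1]); outer <- inner + exp(p[2])
    if (inner < 0.2 || outer > 89) return(.Machine$double.xmax)
    ss_for(inner, outer)
  }
  ss0 <- ss_for(model$inner, model$outer)
  starts <- unique(rbind(
    c(model$inner, model$outer),
    c(5, 25), c(15, 55), c(2, 70)
  ))
  best <- list(value = Inf)
  for (s in seq_len(nrow(starts))) {
    p0 <- c(log(starts[s, 1]), log(starts[s, 2] - starts[s, 1]))
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10))
    if (fit$value < best$value) best <- fit
  }
  improved <- is.finite(best$value) && best$value < ss0 - 1e-12
  if (improved) {
    model$inner <- exp(best$par[1])
    model$outer <- model$inner + exp(best$par[2])
    ss <- best$value
  } else {
    warning("geometry optimization did not improve on the initial guess; keeping it")
    ss <- ss0
  }
  ss_tot <- sum((ly - mean(ly))^2)
  model$calibration <- list(
    inner = model$inner, outer = model$outer,
    ss_residual = ss,
    r_squared = if (ss_tot > 0) 1 - ss / ss_tot else NA_real_,
    improved = improved,
    n_beads = nrow(beads)
  )
  model
}
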