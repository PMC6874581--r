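# Population classification: sequential manual gates (beads, Synechococcus,
# small Crocosphaera), density-based clustering for Prochlorococcus, and a
# scatter/red-fluorescence threshold rule for picoeukaryotes.

POPULATION_LEVELS <- c("beads", "synecho", "croco", "prochloro", "picoeuk", "unknown")
GATE_ORDER <- c("beads", "synecho", "croco")

# TRUE when the closed polygon (n x 2 vertex matrix) has two non-adjacent
# edges that cross.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2 per edge
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  intersects <- function(a, b) {
    d1 <- cross(b[3] - b[1], b[4] - b[2], a[1] - b[1], a[2] - b[2])
    d2 <- cross(b[3] - b[1], b[4] - b[2], a[3] - b[1], a[4] - b[2])
    d3 <- cross(a[3] - a[1], a[4] - a[2], b[1] - a[1], b[2] - a[2])
    d4 <- cross(a[3] - a[1], a[4] - a[2], b[3] - a[1], b[4] - a[2])
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (intersects(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Construct a gating specification
#'
#' A gating spec carries, in fixed order: the manual polygon gates for
#' calibration beads, \emph{Synechococcus} and small \emph{Crocosphaera};
#' the density-clustering parameters for \emph{Prochlorococcus}; and the
#' log10 scatter/red thresholds for picoeukaryotes. All coordinates are in
#' log10 bead-normalized units. Polygons must be simple (non
#' self-intersecting). An optional raw-coordinate bead polygon
#' (\code{bead_gate_raw}) is used to flag beads before normalization
#' exists, during the filtration fit.
#'
#' @param gates named list (\code{beads}, \code{synecho}, \code{croco}),
#'   each a list with \code{channels} (two channel names) and
#'   \code{polygon} (a >= 3 x 2 matrix of vertices in log10 space). Gates
#'   may be omitted.
#' @param cluster_params list with \code{channels} (default
#'   \code{c("fsc", "red")}), \code{grid_n}, \code{mass_fraction} (mass of
#'   the highest-density contour reported as the mode core) and
#'   \code{min_density} (membership cutoff as a fraction of the peak
#'   density).
#' @param picoeuk_thresholds named vector with elements \code{fsc} and
#'   \code{red}: log10 bead-normalized lower thresholds.
#' @param bead_gate_raw optional list like a manual gate but with vertices
#'   in log10 raw instrument units.
#' @return An object of class \code{gating_spec} with a deterministic
#'   \code{gating_id}.
#' @export
gating_spec <- function(gates, cluster_params = list(), picoeuk_thresholds,
                        bead_gate_raw = NULL) {
  gates <- gates[intersect(GATE_ORDER, names(gates))]
  for (nm in names(gates)) {
    g <- gates[[nm]]
    if (!is.matrix(g$polygon) || nrow(g$polygon) < 3 || ncol(g$polygon) != 2)
      stop_cyto("gate '%s': polygon must be a matrix with >= 3 rows and 2 columns", nm)
    if (polygon_self_intersects(g$polygon))
      stop_cyto("gate '%s': polygon is self-intersecting", nm)
    if (length(g$channels) != 2 || !all(g$channels %in% EVENT_CHANNELS))
      stop_cyto("gate '%s': channels must name two event channels", nm)
  }
  cp <- list(channels = cluster_params$channels %||% c("fsc", "red"),
             grid_n = cluster_params$grid_n %||% 128L,
             mass_fraction = cluster_params$mass_fraction %||% 0.9,
             min_density = cluster_params$min_density %||% 0.001,
             bandwidth = cluster_params$bandwidth)
  stopifnot(cp$mass_fraction > 0, cp$mass_fraction < 1,
            cp$min_density > 0, cp$min_density < 1)
  if (!all(c("fsc", "red") %in% names(picoeuk_thresholds)))
    stop_cyto("picoeuk_thresholds must have named elements 'fsc' and 'red'")
  if (!is.null(bead_gate_raw) && polygon_self_intersects(bead_gate_raw$polygon))
    stop_cyto("bead_gate_raw polygon is self-intersecting")
  obj <- structure(list(gates = gates, cluster_params = cp,
                        picoeuk_thresholds = picoeuk_thresholds,
                        bead_gate_raw = bead_gate_raw),
                   class = "gating_spec")
  sig <- paste(
    paste(vapply(names(gates), function(nm) paste(
      nm, paste(gates[[nm]]$channels, collapse = ","),
      num_signature(as.vector(gates[[nm]]$polygon))), character(1)),
      collapse = ";"),
    num_signature(unlist(cp[c("grid_n", "mass_fraction", "min_density")])),
    num_signature(picoeuk_thresholds[c("fsc", "red")]),
    sep = "|")
  obj$gating_id <- hash_id(sig)
  obj
}

#' @export
print.gating_spec <- function(x, ...) {
  cat(sprintf("Gating specification [%s]\n", x$gating_id))
  for (nm in names(x$gates))
    cat(sprintf("  %-8s polygon gate on (%s), %d vertices\n", nm,
                paste(x$gates[[nm]]$channels, collapse = ", "),
                nrow(x$gates[[nm]]$polygon)))
  cat(sprintf("  prochloro: density mode on (%s), membership cutoff %g x peak\n",
              paste(x$cluster_params$channels, collapse = ", "),
              x$cluster_params$min_density))
  cat(sprintf("  picoeuk: log10 fsc > %.2f and log10 red > %.2f\n",
              x$picoeuk_thresholds["fsc"], x$picoeuk_thresholds["red"]))
  invisible(x)
}

# Point-in-polygon membership in log10 channel space.
gate_members <- function(tbl, channels, polygon) {
  x <- log10(tbl[[channels[1]]])
  y <- log10(tbl[[channels[2]]])
  ok <- is.finite(x) & is.finite(y)
  inside <- rep(FALSE, nrow(tbl))
  if (any(ok)) inside[ok] <- mgcv::in.out(rbind(polygon, polygon[1, ]),
                                          cbind(x[ok], y[ok]))
  inside
}

#' Apply sequential manual gates
#'
#' Particles are tested against the manual polygons in fixed order (beads,
#' then \emph{Synechococcus}, then \emph{Crocosphaera}); the first
#' containing polygon wins and gated particles leave the pool for the
#' later, cluster- and threshold-based steps.
#'
#' @param opp an OPP table with strictly positive channels, bead-normalized.
#' @param spec a \code{\link{gating_spec}}.
#' @return Character vector of labels (\code{NA} for still-unassigned
#'   particles).
#' @export
apply_manual_gates <- function(opp, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  labels <- rep(NA_character_, nrow(opp))
  for (nm in names(spec$gates)) {
    g <- spec$gates[[nm]]
    hit <- is.na(labels) & gate_members(opp, g$channels, g$polygon)
    labels[hit] <- nm
  }
  labels
}

# Flood fill of the connected TRUE region (4-neighborhood) containing the
# seed cell of a logical matrix. Linear-index queue, preallocated.
connected_component <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  s <- (seed[2] - 1L) * nr + seed[1]
  if (!mask[s]) return(comp)
  queue <- integer(nr * nc)
  queue[1L] <- s
  head_i <- 1L; tail_i <- 1L
  comp[s] <- TRUE
  while (head_i <= tail_i) {
    cur <- queue[head_i]; head_i <- head_i + 1L
    i <- ((cur - 1L) %% nr) + 1L
    j <- ((cur - 1L) %/% nr) + 1L
    if (i > 1L) { k <- cur - 1L; if (mask[k] && !comp[k]) { comp[k] <- TRUE; tail_i <- tail_i + 1L; queue[tail_i] <- k } }
    if (i < nr) { k <- cur + 1L; if (mask[k] && !comp[k]) { comp[k] <- TRUE; tail_i <- tail_i + 1L; queue[tail_i] <- k } }
    if (j > 1L) { k <- cur - nr; if (mask[k] && !comp[k]) { comp[k] <- TRUE; tail_i <- tail_i + 1L; queue[tail_i] <- k } }
    if (j < nc) { k <- cur + nr; if (mask[k] && !comp[k]) { comp[k] <- TRUE; tail_i <- tail_i + 1L; queue[tail_i] <- k } }
  }
  comp
}

#' Density-based Prochlorococcus clustering
#'
#' Emulates a sequential bivariate gating strategy driven by cell density:
#' a 2-D kernel density estimate is computed on the (log10 fsc, log10 red)
#' plane of the remaining pool, the dominant low-scatter red-fluorescing
#' mode is located at the density maximum (ties broken toward lower
#' scatter), and particles belonging to the mode's connected density region
#' above \code{min_density} times the peak are labeled
#' \code{"prochloro"}. The highest-density contour holding
#' \code{mass_fraction} of the KDE mass around the same mode is reported as
#' the mode core for diagnostics. The procedure is deterministic.
#'
#' @param pool OPP rows not captured by the manual gates (may be empty).
#' @param params cluster parameters from a \code{\link{gating_spec}}.
#' @return Logical vector: \code{TRUE} where the particle is labeled
#'   \emph{Prochlorococcus}; the mode summary is attached as attribute
#'   \code{mode}.
#' @export
cluster_prochloro <- function(pool, params = list()) {
  params <- gating_spec(list(), cluster_params = params,
                        picoeuk_thresholds = c(fsc = 0, red = 0))$cluster_params
  if (nrow(pool) < 10) return(rep(FALSE, nrow(pool)))
  ch <- params$channels
  x <- log10(pool[[ch[1]]])
  y <- log10(pool[[ch[2]]])
  h <- params$bandwidth %||% c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  if (any(h <= 0)) h <- pmax(h, 0.05)
  lims <- c(range(x) + c(-1, 1) * h[1], range(y) + c(-1, 1) * h[2])
  kd <- MASS::kde2d(x, y, h = h, n = params$grid_n, lims = lims)
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  # dominant low-scatter mode: among tied peaks take the smallest fsc
  peak <- peak[order(peak[, 1]), , drop = FALSE][1, ]
  member_mask <- kd$z >= params$min_density * max(kd$z)
  comp <- connected_component(member_mask, peak)
  # diagnostics: highest-density contour holding mass_fraction of the mass
  zs <- sort(as.vector(kd$z), decreasing = TRUE)
  cum <- cumsum(zs) / sum(zs)
  level_mass <- zs[which(cum >= params$mass_fraction)[1]]
  core <- connected_component(kd$z >= level_mass, peak)
  ix <- pmin(pmax(findInterval(x, kd$x, all.inside = TRUE), 1), length(kd$x) - 1)
  iy <- pmin(pmax(findInterval(y, kd$y, all.inside = TRUE), 1), length(kd$y) - 1)
  # snap to the nearer grid line
  ix <- ix + (abs(kd$x[ix + 1] - x) < abs(kd$x[ix] - x))
  iy <- iy + (abs(kd$y[iy + 1] - y) < abs(kd$y[iy] - y))
  members <- comp[cbind(ix, iy)]
  attr(members, "mode") <- list(
    center = c(kd$x[peak[1]], kd$y[peak[2]]),
    peak_density = max(kd$z),
    core_cells = sum(core),
    member_cells = sum(comp))
  members
}

#' Picoeukaryote thresholds and residual labeling
#'
#' Particles in the remaining pool above both the forward-scatter and red
#' fluorescence thresholds (log10 bead-normalized) are labeled
#' \code{"picoeuk"}; everything left becomes \code{"unknown"}.
#'
#' @param pool remaining OPP rows.
#' @param thresholds named vector with \code{fsc} and \code{red}.
#' @return Character vector of labels (\code{"picoeuk"} or
#'   \code{"unknown"}).
#' @export
label_picoeuk <- function(pool, thresholds) {
  if (nrow(pool) == 0) return(character(0))
  hit <- log10(pool$fsc) > thresholds[["fsc"]] & log10(pool$red) > thresholds[["red"]]
  unname(ifelse(hit & is.finite(hit), "picoeuk", "unknown"))
}

#' Classify OPP into populations
#'
#' Runs the full five-step sequence — manual gates for beads,
#' \emph{Synechococcus} and \emph{Crocosphaera}; density clustering for
#' \emph{Prochlorococcus}; scatter/red thresholds for picoeukaryotes — and
#' returns one label per particle, so the labels partition the OPP table.
#'
#' @param opp a bead-normalized OPP table.
#' @param spec a \code{\link{gating_spec}}.
#' @return Factor with levels \code{beads, synecho, croco, prochloro,
#'   picoeuk, unknown} and attribute \code{gating_id}.
#' @export
classify_populations <- function(opp, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  labels <- apply_manual_gates(opp, spec)
  pool_i <- which(is.na(labels))
  pro <- cluster_prochloro(opp[pool_i, , drop = FALSE], spec$cluster_params)
  labels[pool_i[pro]] <- "prochloro"
  pool_i <- which(is.na(labels))
  labels[pool_i] <- label_picoeuk(opp[pool_i, , drop = FALSE],
                                  spec$picoeuk_thresholds)
  out <- factor(labels, levels = POPULATION_LEVELS)
  attr(out, "gating_id") <- spec$gating_id
  out
}

#' Write / read a gating specification
#'
#' Gating specs serialize to YAML: polygons as vertex lists, cluster
#' parameters and thresholds as scalars. Reading re-validates and
#' re-derives the deterministic \code{gating_id}.
#'
#' @param spec a \code{\link{gating_spec}}.
#' @param path YAML file path.
#' @export
write_gating_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gating_spec"))
  ser_gate <- function(g) list(channels = as.list(g$channels),
                               polygon = lapply(seq_len(nrow(g$polygon)),
                                                function(i) as.numeric(g$polygon[i, ])))
  obj <- list(
    gates = lapply(spec$gates, ser_gate),
    cluster_params = spec$cluster_params[c("channels", "grid_n",
                                           "mass_fraction", "min_density")],
    picoeuk_thresholds = as.list(spec$picoeuk_thresholds[c("fsc", "red")]))
  if (!is.null(spec$bead_gate_raw)) obj$bead_gate_raw <- ser_gate(spec$bead_gate_raw)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_gating_spec
#' @export
read_gating_spec <- function(path) {
  if (!file.exists(path)) stop_cyto("gating spec not found: %s", path)
  obj <- yaml::read_yaml(path)
  de_gate <- function(g) list(channels = unlist(g$channels),
                              polygon = do.call(rbind, lapply(g$polygon, as.numeric)))
  gating_spec(lapply(obj$gates, de_gate),
              cluster_params = obj$cluster_params,
              picoeuk_thresholds = unlist(obj$picoeuk_thresholds),
              bead_gate_raw = if (!is.null(obj$bead_gate_raw)) de_gate(obj$bead_gate_raw))
}
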