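# Virtual-core filtration: identify optimally-positioned particles (OPP)
# with two-piece quantile regressions anchored at the 1-micron bead
# coordinates.

# Anchored quantile-regression slope on one segment. x is the log10 forward
# scatter offset from the anchor (one sign per segment), y the detector
# offset. The minimizer of the pinball loss at level tau for a line through
# the origin is a weighted quantile of the per-point ratios y/x with
# weights |x| (level tau for x > 0, 1 - tau for x < 0); loss ties are
# broken toward the smaller slope.
anchored_qr_slope <- function(x, y, tau) {
  stopifnot(length(x) == length(y), all(x > 0) || all(x < 0))
  p <- if (x[1] > 0) tau else 1 - tau
  weighted_quantile_lower(y / x, abs(x), p)
}

#' Fit virtual-core filtration parameters from calibration beads
#'
#' The relationship between forward scatter and each position detector is
#' modeled, in log10 bead-normalized space, as two line segments meeting
#' exactly at the 1-micron bead anchor (the median log10 bead coordinates).
#' Slopes are fit per detector, per segment and per confidence quantile by
#' quantile regression through the fixed anchor, so the q% boundary leaves
#' a fraction q/100 of beads at or below it on each segment. The alignment
#' tolerance is self-calibrated as the 97.5th percentile of the absolute
#' bead log10(d1/d2) ratio.
#'
#' @param events an event table.
#' @param bead_mask logical vector flagging calibration-bead rows; at least
#'   50 flagged rows with strictly positive channels are required.
#' @param quantiles confidence quantiles (percent) to fit.
#' @param min_beads minimum number of flagged rows.
#' @param anchor_window half-width (log10 units) of the forward-scatter
#'   window around the bead scatter mode used to locate the 1-micron
#'   anchor. Calibration runs often contain additional bead sizes; the
#'   anchor must be the coordinates of the primary 1-micron bead cluster
#'   (the densest scatter mode), not the median of the whole bead cloud.
#' @return An object of class \code{filtration_params} with the bead anchor
#'   coordinates, per-detector/segment/quantile slopes, alignment tolerance
#'   and a deterministic \code{filtration_id}.
#' @export
fit_filtration_params <- function(events, bead_mask,
                                  quantiles = c(2.5, 50, 97.5),
                                  min_beads = 50, anchor_window = 0.15) {
  events <- validate_events(events)
  stopifnot(is.logical(bead_mask), length(bead_mask) == nrow(events))
  quantiles <- sort(unique(quantiles))
  if (!all(quantiles > 0 & quantiles < 100))
    stop_cyto("quantiles must be percentages strictly inside (0, 100)")
  beads <- events[bead_mask, , drop = FALSE]
  if (nrow(beads) < min_beads)
    stop_cyto("too few bead rows for filtration fit: %d < %d", nrow(beads), min_beads)
  if (any(beads$d1 <= 0 | beads$d2 <= 0 | beads$fsc <= 0))
    stop_cyto("bead rows must have strictly positive d1, d2 and fsc")
  lfsc <- log10(beads$fsc)
  ld <- list(d1 = log10(beads$d1), d2 = log10(beads$d2))
  # 1-micron bead coordinates: median inside the densest scatter mode, so
  # co-run calibration bead sizes cannot drag the anchor off the cluster
  dens <- stats::density(lfsc)
  mode_lfsc <- dens$x[which.max(dens$y)]
  win <- abs(lfsc - mode_lfsc) <= anchor_window
  if (sum(win) < min(min_beads, 20)) win <- rep(TRUE, length(lfsc))
  anchor <- c(fsc = median(lfsc[win]), d1 = median(ld$d1[win]),
              d2 = median(ld$d2[win]))
  if (sd(lfsc) < 1e-12 || sd(ld$d1) < 1e-12 || sd(ld$d2) < 1e-12)
    stop_cyto("degenerate bead cloud: zero variance in a channel")
  x <- lfsc - anchor["fsc"]
  slopes <- expand.grid(detector = c("d1", "d2"),
                        segment = c("below", "above"),
                        quantile = quantiles,
                        stringsAsFactors = FALSE)
  slopes$slope <- NA_real_
  for (i in seq_len(nrow(slopes))) {
    det <- slopes$detector[i]
    seg <- slopes$segment[i]
    sel <- if (seg == "below") x < 0 else x > 0
    if (sum(sel) < 5)
      stop_cyto("degenerate bead cloud: fewer than 5 beads %s the anchor", seg)
    slopes$slope[i] <- anchored_qr_slope(x[sel], (ld[[det]] - anchor[det])[sel],
                                         slopes$quantile[i] / 100)
  }
  tol <- unname(quantile(abs(ld$d1 - ld$d2), 0.975, type = 7))
  obj <- structure(list(
    anchor = anchor,
    slopes = slopes,
    quantiles = quantiles,
    alignment_tol = tol,
    n_beads = nrow(beads)
  ), class = "filtration_params")
  obj$filtration_id <- hash_id(paste(
    num_signature(anchor), num_signature(slopes$slope),
    num_signature(tol), sep = "|"))
  obj
}

#' @export
print.filtration_params <- function(x, ...) {
  cat(sprintf("Virtual-core filtration parameters [%s]\n", x$filtration_id))
  cat(sprintf("  bead anchor (log10): fsc %.4f, d1 %.4f, d2 %.4f (%d beads)\n",
              x$anchor["fsc"], x$anchor["d1"], x$anchor["d2"], x$n_beads))
  cat(sprintf("  alignment tolerance |log10(d1/d2)| <= %.4f\n", x$alignment_tol))
  for (q in x$quantiles) {
    s <- x$slopes[x$slopes$quantile == q, ]
    cat(sprintf("  q=%4.1f%%: d1 below/above %.4f/%.4f, d2 %.4f/%.4f\n", q,
                s$slope[s$detector == "d1" & s$segment == "below"],
                s$slope[s$detector == "d1" & s$segment == "above"],
                s$slope[s$detector == "d2" & s$segment == "below"],
                s$slope[s$detector == "d2" & s$segment == "above"]))
  }
  invisible(x)
}

# Two-piece boundary for one detector and quantile, evaluated at log10 fsc.
filtration_boundary <- function(params, detector, quantile, lfsc) {
  s <- params$slopes
  b_lo <- s$slope[s$detector == detector & s$segment == "below" & s$quantile == quantile]
  b_hi <- s$slope[s$detector == detector & s$segment == "above" & s$quantile == quantile]
  if (!length(b_lo)) stop_cyto("quantile %s not present in filtration params", quantile)
  x <- lfsc - params$anchor["fsc"]
  unname(params$anchor[detector] + ifelse(x < 0, b_lo, b_hi) * x)
}

#' Select optimally-positioned particles
#'
#' A particle is OPP at confidence quantile q when (i) it is aligned,
#' \code{|log10(d1) - log10(d2)| <= alignment_tol}; and (ii) it scatters
#' more in the forward direction than the bead relationship predicts for
#' both position detectors: \code{log10(d)} at or below the two-piece
#' boundary line for that quantile. Rows with any non-positive channel are
#' excluded before the log transform.
#'
#' @param events an event table.
#' @param params a \code{\link{fit_filtration_params}} object.
#' @param quantile confidence quantile (percent), one of those fit.
#' @return The accepted subset of \code{events}, with a column \code{opp_q}
#'   giving each particle's tightest containing quantile, and attributes
#'   \code{quantile} and \code{filtration_id}.
#' @export
select_opp <- function(events, params, quantile = 50) {
  stopifnot(inherits(params, "filtration_params"))
  if (!quantile %in% params$quantiles)
    stop_cyto("unknown quantile %s; fitted quantiles are %s", quantile,
              paste(params$quantiles, collapse = ", "))
  events <- validate_events(events)
  pos <- events$d1 > 0 & events$d2 > 0 & events$fsc > 0 &
    events$red > 0 & events$orange > 0
  ev <- events[pos, , drop = FALSE]
  ld1 <- log10(ev$d1); ld2 <- log10(ev$d2); lfsc <- log10(ev$fsc)
  aligned <- abs(ld1 - ld2) <= params$alignment_tol
  in_q <- function(q) {
    aligned &
      ld1 <= filtration_boundary(params, "d1", q, lfsc) &
      ld2 <= filtration_boundary(params, "d2", q, lfsc)
  }
  accept <- in_q(quantile)
  opp <- ev[accept, , drop = FALSE]
  # tightest containing quantile per accepted particle
  qlab <- rep(max(params$quantiles), nrow(opp))
  for (q in rev(params$quantiles)) {
    member <- in_q(q)[accept]
    qlab[member] <- q
  }
  opp$opp_q <- qlab
  attr(opp, "quantile") <- quantile
  attr(opp, "filtration_id") <- params$filtration_id
  opp
}

#' Ratio of OPP to total detected particles
#'
#' @param opp the OPP subset for one file.
#' @param events the full event table for the same file.
#' @return The fraction |OPP| / |events| in [0, 1].
#' @export
opp_ratio <- function(opp, events) {
  if (nrow(events) == 0) stop_cyto("cannot compute OPP ratio on an empty event table")
  nrow(opp) / nrow(events)
}
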