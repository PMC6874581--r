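# Virtual-core volume and per-population abundance with flow-rate error
# propagation.

#' Virtual-core volume for one acquisition file
#'
#' The analyzed sample volume is flow rate times acquisition duration; the
#' virtual-core volume is that volume scaled by the OPP-to-total-particle
#' ratio. The flow-rate calibration standard error propagates by the delta
#' method, so the relative standard error of the core volume equals the
#' relative standard error of the flow rate.
#'
#' @param ratio OPP ratio in [0, 1] (see \code{\link{opp_ratio}}).
#' @param meta a one-row slice of the metadata table (needs
#'   \code{flow_rate} in mL/min, \code{flow_rate_se}, \code{duration} in s).
#' @return An object of class \code{core_volume} with \code{sample_volume},
#'   \code{core_volume} and \code{core_volume_se}, all in microliters.
#' @export
virtual_core_volume <- function(ratio, meta) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio < 0 || ratio > 1)
    stop_cyto("OPP ratio must be a single number in [0, 1] (got %s)", format(ratio))
  stopifnot(meta$flow_rate > 0, meta$duration > 0)
  sample_ul <- meta$flow_rate * 1000 / 60 * meta$duration
  core <- ratio * sample_ul
  rel_se <- (meta$flow_rate_se %||% NA_real_) / meta$flow_rate
  if (!is.finite(rel_se)) rel_se <- 0
  structure(list(
    file_id = meta$file_id %||% NA_character_,
    opp_ratio = ratio,
    sample_volume = sample_ul,
    core_volume = core,
    core_volume_se = core * rel_se
  ), class = "core_volume")
}

#' @export
print.core_volume <- function(x, ...) {
  cat(sprintf("Virtual core: %.4g uL of %.4g uL sampled (ratio %.4f), se %.3g uL\n",
              x$core_volume, x$sample_volume, x$opp_ratio, x$core_volume_se))
  invisible(x)
}

#' Cell abundance from a particle count and core volume
#'
#' Abundance is the population count divided by the virtual-core volume.
#' The reported standard error carries only the flow-rate calibration
#' uncertainty (relative SE of the core volume); the Poisson counting
#' error is returned separately in \code{se_count} and is never merged
#' into \code{se}.
#'
#' @param count number of particles in the population (>= 0).
#' @param core a \code{\link{virtual_core_volume}} object.
#' @return List with \code{abundance} (cells per microliter), \code{se}
#'   (flow-rate calibration SE) and \code{se_count} (Poisson SE,
#'   \code{sqrt(count)/core_volume}).
#' @export
abundance <- function(count, core) {
  stopifnot(inherits(core, "core_volume"))
  if (!is_count(count)) stop_cyto("count must be a single non-negative integer")
  if (core$core_volume <= 0) stop_cyto("core volume must be positive to compute abundance")
  ab <- count / core$core_volume
  list(abundance = ab,
       se = ab * core$core_volume_se / core$core_volume,
       se_count = sqrt(count) / core$core_volume)
}
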