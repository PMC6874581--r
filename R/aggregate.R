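# Per-file x per-population summary records and metadata merge.

#' Normalize optical channels to calibration beads
#'
#' Expresses fsc, red and orange in bead-normalized units by dividing each
#' channel by the 1-micron bead reference (typically the per-file median of
#' the bead-gated OPP rows), making channels dimensionless and comparable
#' across files and instruments.
#'
#' @param events event or OPP table.
#' @param ref named vector with \code{fsc}, \code{red}, \code{orange} bead
#'   reference values in raw instrument units (> 0).
#' @return The table with the three channels rescaled.
#' @export
normalize_channels <- function(events, ref) {
  stopifnot(all(c("fsc", "red", "orange") %in% names(ref)), all(ref[c("fsc", "red", "orange")] > 0))
  for (ch in c("fsc", "red", "orange")) events[[ch]] <- events[[ch]] / ref[[ch]]
  events
}

type7_quartiles <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  setNames(q, c("med", "q25", "q75"))
}

#' Summarize one file into per-population records
#'
#' Builds one record per population present in the file: particle count,
#' abundance with flow-rate and Poisson standard errors, and the median /
#' 25th / 75th percentiles (linear-interpolation, type-7 quantiles) of the
#' bead-normalized optical channels, of ESD and of carbon quota at each
#' refractive index. Populations with no particles are omitted.
#'
#' @param assignment factor of population labels, one per OPP row.
#' @param opp the bead-normalized OPP table (rows aligned with
#'   \code{assignment}).
#' @param esd_tables named list (by refractive index, e.g. \code{"1.38"})
#'   of per-particle ESD vectors aligned with \code{opp}.
#' @param carbon_tables same shape, per-particle carbon quotas (fgC).
#' @param core the file's \code{\link{virtual_core_volume}}.
#' @param include_unknown also emit a record for unassigned particles.
#' @return Data frame of per-population summaries for the file.
#' @export
summarize_file <- function(assignment, opp, esd_tables, carbon_tables, core,
                           include_unknown = FALSE) {
  stopifnot(length(assignment) == nrow(opp), inherits(core, "core_volume"))
  stopifnot(all(vapply(esd_tables, length, integer(1)) == nrow(opp)),
            all(vapply(carbon_tables, length, integer(1)) == nrow(opp)))
  pops <- levels(assignment)
  if (!include_unknown) pops <- setdiff(pops, "unknown")
  out <- list()
  for (pop in pops) {
    rows <- which(assignment == pop)
    if (!length(rows)) next
    ab <- abundance(length(rows), core)
    rec <- data.frame(file_id = core$file_id, population = pop,
                      n = length(rows), abundance = ab$abundance,
                      abundance_se = ab$se, abundance_se_count = ab$se_count,
                      stringsAsFactors = FALSE)
    for (ch in c("fsc", "red", "orange")) {
      q <- type7_quartiles(opp[[ch]][rows])
      rec[paste(ch, names(q), sep = "_")] <- as.list(q)
    }
    for (nm in names(esd_tables)) {
      tag <- sprintf("n%03d", round(as.numeric(nm) * 100))
      q <- type7_quartiles(esd_tables[[nm]][rows])
      rec[paste("esd", tag, names(q), sep = "_")] <- as.list(q)
      qc <- type7_quartiles(carbon_tables[[nm]][rows])
      rec[paste("carbon", tag, names(qc), sep = "_")] <- as.list(qc)
    }
    out[[pop]] <- rec
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge summaries with metadata and QC flags
#'
#' Left join of per-population summaries onto the per-file metadata by
#' \code{file_id}; missing environmental values propagate as \code{NA}.
#' A summary whose \code{file_id} has no metadata is an error.
#'
#' @param summaries row-bound output of \code{\link{summarize_file}}.
#' @param meta metadata table.
#' @param qc_flags optional output of \code{\link{flag_instrument}}.
#' @return Records with \code{cruise}, \code{time}, \code{lat}, \code{lon},
#'   environmental columns and instrument flags attached.
#' @export
merge_metadata <- function(summaries, meta, qc_flags = NULL) {
  orphans <- setdiff(unique(summaries$file_id), meta$file_id)
  if (length(orphans))
    stop_cyto("summaries reference file_id(s) with no metadata: %s",
              paste(orphans, collapse = ", "))
  keep <- data.frame(file_id = meta$file_id, cruise = meta$cruise_id,
                     time = meta$timestamp, lat = meta$lat, lon = meta$lon,
                     sst = meta$sst, salinity = meta$salinity, par = meta$par,
                     stringsAsFactors = FALSE)
  out <- merge(summaries, keep, by = "file_id", all.x = TRUE, sort = FALSE)
  if (!is.null(qc_flags))
    out <- merge(out, qc_flags, by = "file_id", all.x = TRUE, sort = FALSE)
  out[order(match(out$file_id, meta$file_id), match(out$population, POPULATION_LEVELS)), ,
      drop = FALSE]
}
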