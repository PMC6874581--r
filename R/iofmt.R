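# Readers/writers: raw event tables, per-file metadata, bead calibration
# tables, gating specs and the final per-population records.

EVENT_CHANNELS <- c("d1", "d2", "fsc", "red", "orange")

#' Validate a per-particle event table
#'
#' An event table holds one row per detected particle with the five optical
#' channels: the two position detectors (\code{d1}, \code{d2}), forward
#' scatter (\code{fsc}), red fluorescence (chlorophyll proxy) and orange
#' fluorescence (phycoerythrin proxy). All channels must be finite and
#' non-negative.
#'
#' @param events a data frame with the five channel columns (a
#'   \code{file_id} column is added if missing).
#' @param file_id identifier of the acquisition file.
#' @return The validated data frame, channels coerced to numeric.
#' @export
validate_events <- function(events, file_id = NULL) {
  missing_cols <- setdiff(EVENT_CHANNELS, names(events))
  if (length(missing_cols))
    stop_cyto("event table schema error: missing column(s) %s",
              paste(missing_cols, collapse = ", "))
  for (ch in EVENT_CHANNELS) {
    v <- suppressWarnings(as.numeric(events[[ch]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop_cyto("event table validation error: column '%s' non-finite or negative at row %d",
                ch, bad[1])
    events[[ch]] <- v
  }
  if (!is.null(file_id)) events$file_id <- file_id
  if (is.null(events$file_id)) events$file_id <- NA_character_
  extra <- setdiff(names(events), c("file_id", EVENT_CHANNELS))
  out <- events[c("file_id", EVENT_CHANNELS, extra)]
  rownames(out) <- NULL
  out
}

#' Read a raw event file
#'
#' @param path file to read.
#' @param dialect \code{"csv"} (header \code{d1,d2,fsc,red,orange}) or
#'   \code{"binary-v1"} (magic bytes \code{CYT1}, version byte 1, unsigned
#'   32-bit little-endian row count, then the five channels as little-endian
#'   doubles in column order).
#' @param file_id identifier recorded in the returned table; defaults to the
#'   file name without extension.
#' @return A validated event table.
#' @export
read_events <- function(path, dialect = c("csv", "binary-v1"), file_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cyto("event file not found: %s", path)
  if (is.null(file_id)) file_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 4, useBytes = TRUE)
    if (!identical(magic, "CYT1"))
      stop_cyto("not a binary-v1 event file (bad magic): %s", path)
    version <- readBin(con, "integer", 1, size = 1, signed = FALSE)
    if (version != 1L) stop_cyto("unsupported binary event file version %d", version)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    vals <- readBin(con, "double", n * 5L, size = 8, endian = "little")
    df <- as.data.frame(matrix(vals, nrow = n, ncol = 5L,
                               dimnames = list(NULL, EVENT_CHANNELS)))
  }
  validate_events(df, file_id = file_id)
}

#' Write a raw event file
#'
#' @param events a validated event table.
#' @param path destination path.
#' @param dialect see \code{\link{read_events}}.
#' @export
write_events <- function(events, path, dialect = c("csv", "binary-v1")) {
  dialect <- match.arg(dialect)
  events <- validate_events(events)
  if (dialect == "csv") {
    write.csv(events[EVENT_CHANNELS], path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("CYT1", con, eos = NULL, useBytes = TRUE)
    writeBin(as.raw(1L), con)
    writeBin(as.integer(nrow(events)), con, size = 4, endian = "little")
    writeBin(as.numeric(as.matrix(events[EVENT_CHANNELS])), con,
             size = 8, endian = "little")
  }
  invisible(path)
}

METADATA_REQUIRED <- c("file_id", "cruise_id", "timestamp", "lat", "lon",
                       "duration", "flow_rate")
METADATA_OPTIONAL <- c("flow_rate_se", "stream_pressure", "event_rate",
                       "sst", "salinity", "par")

#' Read per-file instrument and ship metadata
#'
#' One row per three-minute acquisition file, modeled on underway ship logs:
#' identifier, cruise, UTC timestamp, position, acquisition duration (s),
#' sample-stream flow rate (mL/min) and its standard error, stream pressure
#' (psi), event rate (particles/s), sea-surface temperature, salinity and
#' PAR. Missing environmental fields stay \code{NA} and propagate as such.
#'
#' @param path CSV file.
#' @param flow_rate_se_frac default relative standard error assigned when
#'   \code{flow_rate_se} is absent or missing (flow-rate calibration
#'   uncertainty).
#' @return A data frame sorted by timestamp within cruise.
#' @export
read_metadata <- function(path, flow_rate_se_frac = 0.05) {
  if (!file.exists(path)) stop_cyto("metadata file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df, flow_rate_se_frac = flow_rate_se_frac)
}

#' @rdname read_metadata
#' @param meta a data frame to validate instead of reading from disk.
#' @export
validate_metadata <- function(meta, flow_rate_se_frac = 0.05) {
  missing_cols <- setdiff(METADATA_REQUIRED, names(meta))
  if (length(missing_cols))
    stop_cyto("metadata schema error: missing column(s) %s",
              paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$file_id))
    stop_cyto("duplicate file_id in metadata: %s",
              paste(unique(meta$file_id[duplicated(meta$file_id)]), collapse = ", "))
  if (!inherits(meta$timestamp, "POSIXct"))
    meta$timestamp <- as.POSIXct(meta$timestamp, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(meta$timestamp)) stop_cyto("unparseable timestamp in metadata")
  for (col in METADATA_OPTIONAL) if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  stopifnot(all(meta$duration > 0), all(meta$flow_rate > 0))
  if (any(meta$lat < -90 | meta$lat > 90, na.rm = TRUE) ||
      any(meta$lon < -180 | meta$lon > 180, na.rm = TRUE))
    stop_cyto("latitude/longitude out of range in metadata")
  miss_se <- !is.finite(meta$flow_rate_se)
  meta$flow_rate_se[miss_se] <- flow_rate_se_frac * meta$flow_rate[miss_se]
  for (cr in unique(meta$cruise_id)) {
    idx <- which(meta$cruise_id == cr)
    if (is.unsorted(meta$timestamp[idx], strictly = FALSE))
      warning(sprintf("non-monotone timestamps in cruise %s; applying stable sort", cr))
  }
  meta[order(meta$cruise_id, meta$timestamp), , drop = FALSE]
}

#' Write per-file metadata
#' @param meta metadata data frame.
#' @param path destination CSV.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct or validate a bead calibration table
#'
#' Rows of (diameter in micron, refractive index, measured bead-normalized
#' scatter). Because all scatter is normalized to the 1-micron bead, any
#' 1-micron row must have measured scatter exactly 1.
#'
#' @param diameter bead diameters (micron, > 0), or a data frame with all
#'   three columns.
#' @param refractive_index bead refractive index (recycled).
#' @param measured_norm_scatter measured bead-normalized scatter.
#' @export
bead_table <- function(diameter, refractive_index = 1.60, measured_norm_scatter) {
  df <- data.frame(diameter = diameter,
                   refractive_index = refractive_index,
                   measured_norm_scatter = measured_norm_scatter)
  validate_bead_table(df)
}

validate_bead_table <- function(df) {
  need <- c("diameter", "refractive_index", "measured_norm_scatter")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_cyto("bead table schema error: missing column(s) %s",
              paste(missing_cols, collapse = ", "))
  if (any(df$diameter <= 0)) stop_cyto("bead diameters must be positive")
  one <- abs(df$diameter - 1) < 1e-9
  if (any(one) && any(abs(df$measured_norm_scatter[one] - 1) > 1e-6))
    stop_cyto("1-micron bead rows must have measured_norm_scatter 1 (normalization anchor)")
  df[need]
}

#' @rdname bead_table
#' @param path CSV file with columns diameter, refractive_index,
#'   measured_norm_scatter.
#' @export
read_bead_table <- function(path) {
  if (!file.exists(path)) stop_cyto("bead table not found: %s", path)
  validate_bead_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname bead_table
#' @param beads a bead table to write.
#' @export
write_bead_table <- function(beads, path) {
  write.csv(validate_bead_table(beads), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fixed output column set for the curated per-population records.
population_record_columns <- function(indices = c(1.35, 1.38, 1.41)) {
  idx <- function(prefix) as.vector(t(outer(
    sprintf("%s_n%03d", prefix, round(indices * 100)),
    c("med", "q25", "q75"), paste, sep = "_")))
  c("cruise", "file_id", "time", "lat", "lon", "population", "n",
    "abundance", "abundance_se", "abundance_se_count",
    "fsc_med", "fsc_q25", "fsc_q75",
    "red_med", "red_q25", "red_q75",
    "orange_med", "orange_q25", "orange_q75",
    idx("esd"), idx("carbon"),
    "flag_pressure", "flag_rate",
    "flag_abundance", "flag_esd", "flag_carbon",
    "sst", "salinity", "par")
}

#' Write curated per-population records
#'
#' One CSV row per acquisition file and population, carrying counts,
#' abundance with standard errors, the median/25th/75th percentiles of the
#' optical channels, ESD and carbon quota at each refractive index, QC
#' flags, and the merged ship metadata. The column set and order are fixed
#' across runs.
#'
#' @param records merged records as returned by \code{\link{merge_metadata}}
#'   (or a summary table plus \code{meta} to merge here).
#' @param path destination CSV.
#' @param meta optional metadata to merge when \code{records} are bare
#'   summaries.
#' @param qc_flags optional QC flag table (see \code{\link{flag_instrument}}).
#' @param indices refractive indices present in the summaries.
#' @export
write_population_records <- function(records, path, meta = NULL, qc_flags = NULL,
                                     indices = c(1.35, 1.38, 1.41)) {
  if (!is.null(meta)) records <- merge_metadata(records, meta, qc_flags)
  cols <- population_record_columns(indices)
  missing_cols <- setdiff(cols, names(records))
  for (col in missing_cols) records[[col]] <- NA
  out <- records[cols]
  if (inherits(out$time, "POSIXct"))
    out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 9, format = "g")
    s[!is.finite(v)] <- ""
    s
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read curated per-population records
#' @param path CSV written by \code{\link{write_population_records}}.
#' @export
read_population_records <- function(path) {
  if (!file.exists(path)) stop_cyto("record file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  df$time <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  df
}
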