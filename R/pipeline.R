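# End-to-end pipeline: raw events -> OPP -> populations -> ESD/carbon ->
# abundance -> QC -> curated per-population records.

#' Default pipeline configuration
#'
#' Every knob of the processing chain with its default, as a nested list.
#' User configs (R lists or YAML files) are merged over these defaults.
#'
#' @return Nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    dialect = "csv",
    quantile = 50,
    refractive_indices = c(1.35, 1.38, 1.41),
    mie = list(wavelength = 457, n_medium = 1.34, n_bead = 1.60,
               inner = 2, outer = 15, grid_n = 2000, calibrate = TRUE),
    filtration = list(min_beads = 50, quantiles = c(2.5, 50, 97.5)),
    normalization = list(min_beads_per_file = 20),
    flow_rate_se_frac = 0.05,
    qc = list(pressure_tol = 0.05, rate_max = 18000),
    include_unknown = FALSE,
    # channel role -> filter mapping, recorded as configuration; roles
    # (chlorophyll -> red, phycoerythrin -> orange) drive all processing
    filter_map = list(fsc = "457/50", red = "692/40", orange = "572/28")
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load a pipeline configuration
#'
#' @param config a YAML file path or a named list; merged over
#'   \code{\link{pipeline_defaults}}.
#' @export
load_pipeline_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(pipeline_defaults(), user)
  for (req in c("input_dir", "metadata", "bead_table", "gating_spec", "output_dir"))
    if (is.null(cfg[[req]])) stop_cyto("pipeline config is missing '%s'", req)
  cfg
}

pipeline_stage <- function(stage, file_id = NA, expr) {
  tryCatch(expr, error = function(e) {
    stop_cyto("pipeline stage '%s' failed%s: %s", stage,
              if (is.na(file_id)) "" else sprintf(" on file %s", file_id),
              conditionMessage(e))
  })
}

#' Run the full processing pipeline
#'
#' Executes filtration, classification, Mie sizing, quantification, QC and
#' aggregation over a directory of raw event files, writing the curated
#' per-population CSV, a parameter record (filtration and gating
#' identification numbers, calibrated geometry) and a machine-readable run
#' log. Re-running with identical inputs reproduces identical curated
#' output. Any stage failure aborts with the stage name and offending
#' file.
#'
#' @param config YAML path or list; see \code{\link{load_pipeline_config}}.
#'   Required entries: \code{input_dir}, \code{metadata} (CSV),
#'   \code{bead_table} (CSV), \code{gating_spec} (YAML),
#'   \code{output_dir}.
#' @return Invisibly, a list with the curated \code{records}, QC'd
#'   metadata, fitted parameters and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.jsonl")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log_event <- function(stage, ...) {
    writeLines(jsonlite::toJSON(c(list(stage = stage), list(...)),
                                auto_unbox = TRUE, digits = NA), log_con)
  }

  meta <- pipeline_stage("metadata", NA,
    read_metadata(cfg$metadata, flow_rate_se_frac = cfg$flow_rate_se_frac))
  beads_tbl <- pipeline_stage("bead_table", NA, read_bead_table(cfg$bead_table))
  gspec <- pipeline_stage("gating_spec", NA, read_gating_spec(cfg$gating_spec))
  if (is.null(gspec$bead_gate_raw))
    stop_cyto("pipeline stage 'gating_spec' failed: a bead_gate_raw polygon is required to flag beads")
  ext <- if (cfg$dialect == "csv") "\\.csv$" else "\\.bin$"
  paths <- sort(list.files(cfg$input_dir, pattern = ext, full.names = TRUE))
  if (!length(paths)) stop_cyto("pipeline stage 'input' failed: no event files in %s", cfg$input_dir)
  log_event("input", n_files = length(paths), gating_id = gspec$gating_id)

  # Mie model: calibrate acceptance geometry on the bead ladder, then build
  # one monotone lookup per cell refractive index.
  model <- pipeline_stage("mie_calibration", NA, {
    m <- mie_model(wavelength = cfg$mie$wavelength, n_medium = cfg$mie$n_medium,
                   n_cells = cfg$refractive_indices, n_bead = cfg$mie$n_bead,
                   inner = cfg$mie$inner, outer = cfg$mie$outer,
                   grid_n = cfg$mie$grid_n)
    if (isTRUE(cfg$mie$calibrate)) calibrate_geometry(beads_tbl, m) else m
  })
  lookups <- pipeline_stage("mie_lookup", NA, {
    lk <- lapply(cfg$refractive_indices, function(n) build_lookup(model, n))
    names(lk) <- format(cfg$refractive_indices)
    lk
  })
  log_event("mie", inner = model$inner, outer = model$outer,
            r_squared = model$calibration$r_squared)

  events <- list()
  for (p in paths) {
    ev <- pipeline_stage("read_events", basename(p), read_events(p, dialect = cfg$dialect))
    fid <- ev$file_id[1]
    if (!fid %in% meta$file_id)
      stop_cyto("pipeline stage 'read_events' failed on file %s: no metadata row", fid)
    events[[fid]] <- ev
  }

  # filtration parameters fit once per run on the pooled bead-gated rows
  all_ev <- do.call(rbind, events)
  bead_mask <- pipeline_stage("filtration", NA,
    gate_members(all_ev, gspec$bead_gate_raw$channels, gspec$bead_gate_raw$polygon))
  fparams <- pipeline_stage("filtration", NA,
    fit_filtration_params(all_ev, bead_mask, quantiles = cfg$filtration$quantiles,
                          min_beads = cfg$filtration$min_beads))
  log_event("filtration", filtration_id = fparams$filtration_id,
            n_beads = fparams$n_beads, alignment_tol = fparams$alignment_tol)

  # pooled bead reference for files with too few beads of their own
  pooled_opp <- pipeline_stage("filtration", NA, select_opp(all_ev, fparams, cfg$quantile))
  pooled_bead_rows <- gate_members(pooled_opp, gspec$bead_gate_raw$channels,
                                   gspec$bead_gate_raw$polygon)
  pooled_ref <- vapply(c("fsc", "red", "orange"),
                       function(ch) median(pooled_opp[[ch]][pooled_bead_rows]),
                       numeric(1))
  if (any(!is.finite(pooled_ref) | pooled_ref <= 0))
    stop_cyto("pipeline stage 'normalization' failed: no usable bead reference")

  summaries <- list()
  for (fid in names(events)) {
    ev <- events[[fid]]
    opp <- pipeline_stage("filtration", fid, select_opp(ev, fparams, cfg$quantile))
    ratio <- pipeline_stage("quantify", fid, opp_ratio(opp, ev))
    mrow <- meta[meta$file_id == fid, , drop = FALSE]
    core <- pipeline_stage("quantify", fid, virtual_core_volume(ratio, mrow))
    bead_rows <- gate_members(opp, gspec$bead_gate_raw$channels,
                              gspec$bead_gate_raw$polygon)
    ref <- if (sum(bead_rows) >= cfg$normalization$min_beads_per_file) {
      vapply(c("fsc", "red", "orange"),
             function(ch) median(opp[[ch]][bead_rows]), numeric(1))
    } else pooled_ref
    opp_n <- pipeline_stage("normalization", fid, normalize_channels(opp, ref))
    labels <- pipeline_stage("classification", fid, classify_populations(opp_n, gspec))
    esd_tables <- list(); carbon_tables <- list()
    for (nm in names(lookups)) {
      inv <- pipeline_stage("sizing", fid, scatter_to_esd(opp_n$fsc, lookups[[nm]]))
      esd_tables[[nm]] <- inv$esd
      carbon_tables[[nm]] <- carbon_from_volume(esd_to_volume(inv$esd))
    }
    summaries[[fid]] <- pipeline_stage("aggregate", fid,
      summarize_file(labels, opp_n, esd_tables, carbon_tables, core,
                     include_unknown = cfg$include_unknown))
    log_event("file", file_id = fid, n_events = nrow(ev), n_opp = nrow(opp),
              opp_ratio = ratio, core_volume = core$core_volume)
  }

  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  qc_flags <- pipeline_stage("qc", NA,
    flag_instrument(meta, pressure_tol = cfg$qc$pressure_tol,
                    rate_max = cfg$qc$rate_max))
  records <- pipeline_stage("aggregate", NA, merge_metadata(summaries, meta, qc_flags))
  records <- pipeline_stage("qc", NA, qc_screen(records))

  out_csv <- file.path(cfg$output_dir, "population_records.csv")
  pipeline_stage("output", NA,
    write_population_records(records, out_csv, indices = cfg$refractive_indices))
  params_path <- file.path(cfg$output_dir, "parameters.json")
  jsonlite::write_json(list(
    filtration_id = fparams$filtration_id,
    gating_id = gspec$gating_id,
    quantile = cfg$quantile,
    alignment_tol = fparams$alignment_tol,
    anchor = as.list(fparams$anchor),
    slopes = fparams$slopes,
    mie = list(wavelength = model$wavelength, n_medium = model$n_medium,
               inner = model$inner, outer = model$outer,
               r_squared = model$calibration$r_squared),
    filter_map = cfg$filter_map
  ), params_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_event("done", records = nrow(records), output = out_csv)

  invisible(list(records = records, metadata = meta, qc_flags = qc_flags,
                 filtration = fparams, gating = gspec, model = model,
                 paths = list(records = out_csv, parameters = params_path,
                              log = log_path)))
}
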