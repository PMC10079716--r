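# File interchange: measurement CSV (schema fixed to the single-letter
# measurement symbols for traceability), study manifest JSON (carries the
# simulation truth separately so calibration code can never read it), and a
# YAML run configuration.

.meas_cols <- c("series_id", "rotation_deg",
                "a", "b", "c", "d", "h", "i", "k", "m", "n", "o", "p")

#' Write / read the measurement table
#'
#' CSV with one row per radiograph set and columns exactly
#' `series_id, rotation_deg, a, b, c, d, h, i, k, m, n, o, p` (mm); missing
#' fields are empty.
#'
#' @param df A measurement data frame (e.g. from [measurements_table()]).
#' @param path File path.
#'
#' @return `write_measurements` returns `path` invisibly; `read_measurements`
#'   returns the validated data frame.
#' @export
write_measurements <- function(df, path) {
  missing_cols <- setdiff(.meas_cols, names(df))
  if (length(missing_cols)) {
    stop("measurement table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(df[, .meas_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable measurement file: ", path,
                             call. = FALSE))
  if (nrow(df) == 0L) {
    stop("measurement file contains no rows: ", path, call. = FALSE)
  }
  missing_cols <- setdiff(.meas_cols, names(df))
  if (length(missing_cols)) {
    stop("measurement file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(.meas_cols, "series_id")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  bad <- which(vapply(seq_len(nrow(df)), function(r) {
    any(!is.na(unlist(df[r, num_cols])) & unlist(df[r, num_cols]) < 0)
  }, logical(1L)))
  if (length(bad)) {
    stop("negative measurements in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df[, .meas_cols]
}

#' Write the study manifest
#'
#' JSON manifest listing every exposure with its design factors and
#' simulation truth (true hip-plane calibration factor, marker depths). Kept
#' separate from the measurement CSV so the calibration pipeline can never
#' consume truth values.
#'
#' @param records A `study_records` list.
#' @param path File path.
#'
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  stopifnot(inherits(records, "study_records"))
  entries <- lapply(records, function(r) {
    list(series_id = r$series_id, view = r$view,
         anterior_mm = r$anterior_mm, lateral_mm = r$lateral_mm,
         rotation_deg = r$rotation_deg, truth = r$truth)
  })
  jsonlite::write_json(list(n_exposures = length(records),
                            exposures = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Default run configuration
#'
#' Fully serializable description of one tool run: beam geometries, phantom,
#' noise model, solver settings, design grid and seed. A persisted
#' configuration re-runs to identical outputs for noiseless or seeded runs.
#'
#' @param seed Integer seed controlling all randomness of the run.
#' @param noise Logical: simulate measurement noise?
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, noise = FALSE) {
  structure(list(
    beam = list(sdd_ap_mm = 1150, sdd_lat_mm = 1150),
    phantom = unclass(phantom_config()),
    noise = list(enabled = noise, sd_distance_mm = 0.2, sd_axis_mm = 0.15),
    solver = list(tol_pp = 1e-4, max_iter = 100L),
    design = list(anterior_mm = c(20, 50, 80),
                  lateral_mm = c(0, 20, 40, 60),
                  rotations_deg = c(0, 10, 20, 30)),
    threshold_pp = 1.5,
    seed = as.integer(seed)),
    class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @param config A `run_config` list.
#'
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (sec in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
      if (length(bad)) {
        stop("unknown config keys in `", sec, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config sections: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # validate by construction
  do.call(phantom_config, cfg$phantom)
  beam_geometry(cfg$beam$sdd_ap_mm)
  beam_geometry(cfg$beam$sdd_lat_mm)
  solver_settings(cfg$solver$tol_pp, cfg$solver$max_iter)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_parts <- function(config) {
  list(g_ap = beam_geometry(config$beam$sdd_ap_mm),
       g_lat = beam_geometry(config$beam$sdd_lat_mm),
       phantom = do.call(phantom_config, config$phantom),
       settings = solver_settings(config$solver$tol_pp,
                                  config$solver$max_iter),
       noise = if (isTRUE(config$noise$enabled)) {
         noise_model(config$noise$sd_distance_mm, config$noise$sd_axis_mm,
                     seed = config$seed)
       } else NULL)
}
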