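# Reading, validating and writing the time-series and tabular formats the
# pipeline touches, plus the recording/trial containers.

#' Sensor sites
#'
#' The five mounting sites of the sensor array: one unit laterally on each
#' cannon bone (left/right fore, left/right hind) and one on the saddle girth
#' over the sternum (trunk).
#'
#' @format Character vectors of site codes.
#' @export
sensor_sites <- c("LF", "RF", "LH", "RH", "TRUNK")

#' @rdname sensor_sites
#' @export
limb_sites <- c("LF", "RF", "LH", "RH")

#' Gait labels accepted in trial metadata
#' @export
gait_levels <- c("walk", "trot", "canter_left", "canter_right")

# Canonical CSV column dialect (one file per sensor).
imu_required_cols <- c("time_s", "acc_x", "acc_y", "acc_z",
                       "gyr_x", "gyr_y", "gyr_z")
imu_euler_cols <- c("roll_deg", "pitch_deg", "yaw_deg")

#' Construct and validate an IMU recording
#'
#' An IMU recording is a tibble with columns `time_s`, `acc_x/y/z` (in g,
#' 1 g = 9.81 m s^-2), `gyr_x/y/z` (deg/s) and optionally `roll_deg`,
#' `pitch_deg`, `yaw_deg`, carrying the sensor site and nominal sampling rate
#' as attributes. Time is stored relative to the first sample.
#'
#' @param data Data frame with the canonical columns.
#' @param site One of [sensor_sites].
#' @param rate_hz Nominal sampling rate (default 120 Hz).
#' @return A validated `imu_recording` tibble.
#' @export
imu_recording <- function(data, site, rate_hz = 120) {
  site <- match.arg(site, sensor_sites)
  data <- as_tibble(data)
  missing_cols <- setdiff(imu_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "eqg_format_error")
  }
  has_euler <- all(imu_euler_cols %in% names(data))
  keep <- c(imu_required_cols, if (has_euler) imu_euler_cols)
  data <- data[, keep]
  num <- as.matrix(data)
  if (!all(is.finite(num))) {
    abort("non-finite values in recording", class = "eqg_data_error")
  }
  if (nrow(data) < 2) {
    abort("recording must have at least 2 samples", class = "eqg_data_error")
  }
  dt <- diff(data$time_s)
  if (any(dt <= 0)) {
    abort("time vector is not strictly increasing", class = "eqg_data_error")
  }
  if (abs(median(dt) - 1 / rate_hz) > 0.05 / rate_hz) {
    abort(sprintf(
      "median sampling interval %.5f s deviates >5%% from nominal 1/%g s",
      median(dt), rate_hz), class = "eqg_data_error")
  }
  if (has_euler && any(data$pitch_deg < -90 | data$pitch_deg > 90)) {
    abort("pitch angle outside [-90, 90] degrees", class = "eqg_data_error")
  }
  data$time_s <- data$time_s - data$time_s[1]
  structure(data,
            site = site, rate_hz = rate_hz,
            class = c("imu_recording", class(data)))
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> site %s, %d samples @ %g Hz%s\n",
              attr(x, "site"), nrow(x), attr(x, "rate_hz"),
              if ("pitch_deg" %in% names(x)) ", with orientation" else ""))
  NextMethod()
}

rec_site <- function(rec) attr(rec, "site")
rec_rate <- function(rec) attr(rec, "rate_hz")

#' Read one sensor's CSV export
#'
#' Expects the canonical dialect `time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y,
#' gyr_z[, roll_deg, pitch_deg, yaw_deg]`; vendor exports with other headers
#' can be mapped via `col_map`. Accelerations are stored internally in g.
#' With `unit_hint = "auto"` the resting magnitude -- the norm of the
#' per-axis medians, i.e. the gravity vector -- decides: a value in [8, 12]
#' means the file was in m s^-2 (divided by 9.81), in [0.8, 1.2] it was
#' already in g.
#'
#' @param path CSV file path.
#' @param site One of [sensor_sites].
#' @param unit_hint `"auto"`, `"g"` or `"ms2"`.
#' @param rate_hz Nominal sampling rate.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(time_s = "PacketTime")`.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, site, unit_hint = c("auto", "g", "ms2"),
                           rate_hz = 120, col_map = NULL) {
  unit_hint <- match.arg(unit_hint)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "eqg_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(imu_required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "eqg_format_error")
  }
  acc <- as.matrix(df[, c("acc_x", "acc_y", "acc_z")])
  scale <- switch(unit_hint,
    g = 1,
    ms2 = 1 / 9.81,
    auto = {
      # resting magnitude = norm of the per-axis medians: each axis spends
      # most of its time near the gravity baseline, noise and rhythmic
      # oscillations are symmetric and impact transients sparse, so the
      # median recovers the gravity vector even in vigorous trials
      mode_mag <- sqrt(sum(apply(acc, 2, median)^2))
      if (mode_mag >= 8 && mode_mag <= 12) {
        1 / 9.81
      } else if (mode_mag >= 0.8 && mode_mag <= 1.2) {
        1
      } else {
        abort(sprintf(
          "cannot resolve acceleration units: magnitude mode %.3f is neither near 1 g nor near 9.81 m/s^2",
          mode_mag), class = "eqg_unit_error")
      }
    })
  df$acc_x <- df$acc_x * scale
  df$acc_y <- df$acc_y * scale
  df$acc_z <- df$acc_z * scale
  imu_recording(df, site = site, rate_hz = rate_hz)
}


#' Write a recording to the canonical CSV dialect
#'
#' @param rec An [imu_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(as_tibble(as.data.frame(rec)), path, progress = FALSE)
  invisible(path)
}

#' Trial metadata
#'
#' @param horse_id Subject identifier.
#' @param gait One of [gait_levels]. Canter must match the rein: left-lead
#'   canter is ridden on the left rein, right-lead on the right.
#' @param rein `"left"` or `"right"`.
#' @param duration_s Nominal trial length in seconds (default 40).
#' @param surface Free-text footing description.
#' @return A `trial_meta` list.
#' @export
trial_meta <- function(horse_id, gait, rein, duration_s = 40,
                       surface = "sand") {
  gait <- match.arg(gait, gait_levels)
  rein <- match.arg(rein, c("left", "right"))
  if (gait == "canter_left" && rein != "left") {
    abort("canter_left is only valid on the left rein", class = "eqg_meta_error")
  }
  if (gait == "canter_right" && rein != "right") {
    abort("canter_right is only valid on the right rein", class = "eqg_meta_error")
  }
  structure(list(horse_id = as.character(horse_id), gait = gait, rein = rein,
                 duration_s = duration_s, surface = surface),
            class = "trial_meta")
}

#' Bundle one trial's recordings
#'
#' All four limb sites must be present; the trunk sensor is optional. All
#' recordings must overlap on a common window of at least 5 s.
#'
#' @param recordings Named list of [imu_recording()]s, names in [sensor_sites].
#' @param meta A [trial_meta()].
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(recordings, meta) {
  stopifnot(inherits(meta, "trial_meta"))
  missing_sites <- setdiff(limb_sites, names(recordings))
  if (length(missing_sites) > 0) {
    abort(paste0("missing limb recording(s): ",
                 paste(missing_sites, collapse = ", ")),
          class = "eqg_data_error")
  }
  spans <- vapply(recordings, function(r) diff(range(r$time_s)), numeric(1))
  if (min(spans) < 5) {
    abort("recordings must overlap on a common window of at least 5 s",
          class = "eqg_data_error")
  }
  structure(list(meta = meta, recordings = recordings),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> horse %s, %s, %s rein: %s\n",
              x$meta$horse_id, x$meta$gait, x$meta$rein,
              paste(names(x$recordings), collapse = " ")))
  invisible(x)
}

stride_table_cols <- c("horse_id", "gait", "rein", "limb",
                       "cycle_start_s", "hoof_on_s", "hoof_off_s",
                       "cycle_end_s", "stance_ms", "swing_ms", "stride_s",
                       "stride_freq_hz", "duty_factor", "pill_g")

#' Write / read the per-stride table
#'
#' One row per detected gait cycle with the columns `horse_id, gait, rein,
#' limb, cycle_start_s, hoof_on_s, hoof_off_s, cycle_end_s, stance_ms,
#' swing_ms, stride_s, stride_freq_hz, duty_factor, pill_g`.
#'
#' @param cycles Tibble of gait cycles with stride parameters and trial
#'   identifiers (see [stride_parameters()]).
#' @param path Output CSV path.
#' @return Number of rows written.
#' @export
write_stride_table <- function(cycles, path) {
  if (is.null(cycles) || nrow(as_tibble(cycles)) == 0) {
    empty <- as_tibble(setNames(
      as.list(rep(list(numeric(0)), length(stride_table_cols))),
      stride_table_cols))
    for (col in c("horse_id", "gait", "rein", "limb")) {
      empty[[col]] <- character(0)
    }
    readr::write_csv(empty, path, progress = FALSE)
    return(0L)
  }
  cycles <- as_tibble(cycles)
  missing_cols <- setdiff(stride_table_cols, names(cycles))
  if (length(missing_cols) > 0) {
    abort(paste0("stride table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "eqg_format_error")
  }
  out <- cycles[, stride_table_cols]
  readr::write_csv(out, path, progress = FALSE)
  nrow(out)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a trial manifest
#'
#' A trial manifest is a YAML file with the [trial_meta()] fields plus a
#' `sensors:` mapping of site codes to CSV paths (relative to the manifest).
#'
#' @param path Manifest YAML path.
#' @param unit_hint Passed to [read_recording()].
#' @param rate_hz Nominal sampling rate.
#' @return A [trial_recording()].
#' @export
read_trial_manifest <- function(path, unit_hint = "auto", rate_hz = 120) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "eqg_io_error")
  }
  man <- yaml::read_yaml(path)
  req <- c("horse_id", "gait", "rein", "sensors")
  if (!all(req %in% names(man))) {
    abort("manifest must name horse_id, gait, rein and sensors",
          class = "eqg_format_error")
  }
  meta <- trial_meta(man$horse_id, man$gait, man$rein,
                     duration_s = man$duration_s %||% 40,
                     surface = man$surface %||% "unknown")
  base <- dirname(path)
  recs <- lapply(names(man$sensors), function(site) {
    p <- man$sensors[[site]]
    if (!grepl("^/", p)) p <- file.path(base, p)
    read_recording(p, site = site, unit_hint = unit_hint, rate_hz = rate_hz)
  })
  names(recs) <- names(man$sensors)
  trial_recording(recs, meta)
}

#' Write a trial (per-sensor CSVs plus manifest) to a directory
#'
#' @param trial A [trial_recording()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sensors <- list()
  for (site in names(trial$recordings)) {
    f <- paste0(site, ".csv")
    write_recording(trial$recordings[[site]], file.path(dir, f))
    sensors[[site]] <- f
  }
  man <- c(unclass(trial$meta), list(sensors = sensors))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
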