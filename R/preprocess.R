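# Rotation-invariant acceleration magnitude, zero-phase Butterworth low-pass,
# and global-frame pitch angle.

#' Low-pass filter specification
#'
#' @param order Butterworth order (default 2).
#' @param cutoff_hz Cutoff frequency in Hz (default 20); must lie below the
#'   Nyquist frequency `rate_hz / 2`.
#' @param rate_hz Sampling rate in Hz (default 120).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 2, cutoff_hz = 20, rate_hz = 120) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    abort("cutoff must satisfy 0 < cutoff_hz < rate_hz / 2",
          class = "eqg_parameter_error")
  }
  if (order < 1) abort("filter order must be >= 1", class = "eqg_parameter_error")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz), class = "filter_spec")
}

#' Euclidean acceleration magnitude
#'
#' The magnitude of the tri-axial acceleration vector,
#' sqrt(ax^2 + ay^2 + az^2). Being a norm it is invariant under any rotation
#' of the sensor's coordinate system, so the exact mounting orientation is
#' irrelevant for the load measures built on it.
#'
#' @param acc An N x 3 matrix, a 3 x N matrix, or a data frame containing
#'   `acc_x`, `acc_y`, `acc_z` (units of g).
#' @return Numeric vector of magnitudes (g).
#' @export
acceleration_magnitude <- function(acc) {
  if (is.data.frame(acc)) {
    acc <- as.matrix(acc[, c("acc_x", "acc_y", "acc_z")])
  }
  if (!is.matrix(acc)) abort("acc must be a matrix or data frame",
                             class = "eqg_data_error")
  if (ncol(acc) != 3 && nrow(acc) == 3) acc <- t(acc)
  if (ncol(acc) != 3) abort("acc must have 3 columns (or 3 rows)",
                            class = "eqg_data_error")
  if (!all(is.finite(acc))) abort("non-finite acceleration input",
                                  class = "eqg_data_error")
  sqrt(rowSums(acc^2))
}

#' Zero-phase Butterworth low-pass
#'
#' Applies the Butterworth filter forward and backward (`signal::filtfilt`),
#' so the output has zero phase lag: detected event times are not shifted by
#' the filter. The effective magnitude response is the squared single-pass
#' response.
#'
#' @param x Numeric vector.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @export
lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (length(x) <= 3 * spec$order) {
    abort("signal too short for the requested filter order",
          class = "eqg_parameter_error")
  }
  if (!all(is.finite(x))) abort("non-finite signal", class = "eqg_data_error")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$rate_hz / 2),
                       type = "low")
  # odd-reflection padding so the filter state is settled at both edges
  n <- length(x)
  npad <- min(n - 1, max(3 * ceiling(spec$rate_hz / spec$cutoff_hz),
                         9 * spec$order))
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(npad + 1):(npad + n)]
}

#' Pitch angle relative to the global horizontal plane
#'
#' Returns the inclination of the sensor x-axis from horizontal, in degrees,
#' positive when the x-axis points above the horizon. If the recording has an
#' orientation (Euler) channel, its pitch is returned directly. Otherwise the
#' gravity direction is isolated with a 2 Hz low-pass on each accelerometer
#' axis (stride content lies at or above ~0.8 Hz and impact transients far
#' above it) and pitch is estimated as asin(ax_lp / |a_lp|): a resting sensor
#' with its x-axis vertical reads +1 g on x and +90 degrees of pitch.
#'
#' @param rec An [imu_recording()].
#' @param gravity_cutoff_hz Low-pass cutoff for the gravity estimate.
#' @return Numeric vector of pitch angles in degrees, range \[-90, 90\].
#' @export
pitch_angle <- function(rec, gravity_cutoff_hz = 2) {
  if ("pitch_deg" %in% names(rec)) {
    return(rec$pitch_deg)
  }
  spec <- filter_spec(order = 2, cutoff_hz = gravity_cutoff_hz,
                      rate_hz = rec_rate(rec))
  ax <- lowpass(rec$acc_x, spec)
  ay <- lowpass(rec$acc_y, spec)
  az <- lowpass(rec$acc_z, spec)
  norm <- sqrt(ax^2 + ay^2 + az^2)
  low <- norm < 0.3
  if (any(low)) {
    # sustained (>0.25 s) loss of the gravity vector is unrecoverable
    run <- rle(low)
    if (any(run$lengths[run$values] > 0.25 * rec_rate(rec))) {
      abort("gravity magnitude below 0.3 g for a sustained window; cannot estimate pitch",
            class = "eqg_estimation_error")
    }
  }
  asin(pmin(1, pmax(-1, ax / norm))) * 180 / pi
}
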