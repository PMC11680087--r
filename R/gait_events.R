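# Stride segmentation and hoof-on / hoof-off event detection.
#
# The cycle period is first estimated from the oscillating pitch angle; the
# peaks of the low-passed sagittal-plane angular velocity (one protraction
# lobe per swing phase) then delimit gait cycles, each beginning in the swing
# phase; within each cycle the first acceleration-magnitude peak marks
# hoof-on and the most prominent later peak marks hoof-off.

#' Find local maxima with prominence
#'
#' Plain peak picking used throughout the event detection: local maxima,
#' optionally thresholded on height and topographic prominence, thinned to a
#' minimum separation (keeping higher peaks first).
#'
#' @param x Numeric vector.
#' @param min_separation Minimum distance between kept peaks, in samples.
#' @param min_height Minimum peak height.
#' @param min_prominence Minimum prominence: peak height minus the higher of
#'   the two minima separating it from higher terrain on each side.
#' @return Tibble with `index`, `height`, `prominence`, ordered by index.
#' @export
find_peaks <- function(x, min_separation = 1, min_height = -Inf,
                       min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(tibble(index = integer(), height = numeric(),
                           prominence = numeric()))
  core <- x[2:(n - 1)]
  is_pk <- core > x[1:(n - 2)] & core >= x[3:n]
  idx <- which(is_pk) + 1L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) == 0) {
    return(tibble(index = integer(), height = numeric(),
                  prominence = numeric()))
  }
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) > 1 && min_separation > 1) {
    ord <- order(x[idx], decreasing = TRUE)
    kept <- integer(0)
    for (j in ord) {
      if (all(abs(idx[j] - kept) >= min_separation)) kept <- c(kept, idx[j])
    }
    sel <- idx %in% kept
    idx <- idx[sel]; prom <- prom[sel]
  }
  o <- order(idx)
  tibble(index = idx[o], height = x[idx[o]], prominence = prom[o])
}

# Height above the higher of the two key saddles: on each side, walk outward
# until a sample exceeds the peak (or the signal ends) and take the minimum
# over that stretch.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i == 1) h else {
    j <- i - 1; m <- x[j]
    while (j > 1 && x[j] <= h) { j <- j - 1; m <- min(m, x[j]) }
    m
  }
  right <- if (i == length(x)) h else {
    j <- i + 1; m <- x[j]
    while (j < length(x) && x[j] <= h) { j <- j + 1; m <- min(m, x[j]) }
    m
  }
  h - max(left, right)
}

#' Estimate the gait-cycle period from an oscillating pitch angle
#'
#' The dominant stride rhythm is read off the periodogram of the demeaned
#' pitch trace: the highest non-DC spectral peak in the 0.4-2.5 Hz search band
#' (equine stride frequencies in walk-canter fall well inside it). The FFT is
#' zero-padded 4x for frequency resolution.
#'
#' @param pitch Numeric vector of pitch angles (degrees).
#' @param rate_hz Sampling rate.
#' @param band Frequency search band in Hz.
#' @param min_peak_ratio Reject as "no gait" unless the band maximum exceeds
#'   this multiple of the median in-band spectral power.
#' @return Estimated cycle period in seconds.
#' @export
estimate_cycle_period <- function(pitch, rate_hz = 120,
                                  band = c(0.4, 2.5), min_peak_ratio = 3) {
  n <- length(pitch)
  if (n < 5 * rate_hz) {
    abort("need at least 5 s of data to estimate the cycle period",
          class = "eqg_data_error")
  }
  x <- pitch - mean(pitch)
  nfft <- 4 * 2^ceiling(log2(n))
  p <- Mod(fft(c(x, rep(0, nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) * rate_hz / nfft
  in_band <- freqs >= band[1] & freqs <= band[2]
  pb <- p[in_band]; fb <- freqs[in_band]
  if (max(pb) < min_peak_ratio * median(pb) || max(pb) <= 0) {
    abort("no dominant oscillation in the gait band; is the horse moving?",
          class = "eqg_no_gait_error")
  }
  1 / fb[which.max(pb)]
}

#' Segment gait cycles from sagittal-plane angular velocity
#'
#' The input is the sign-normalised sagittal angular velocity (limb
#' protraction positive; see [sagittal_angular_velocity()]). After the 20 Hz
#' zero-phase low-pass, peaks -- one per swing phase -- are picked with a
#' minimum separation of `min_sep_frac` times the period hint and a minimum
#' prominence of `prom_frac` times the 95th-percentile amplitude (floored at
#' 5% of the maximum amplitude, for numerically quiet traces). Consecutive
#' peaks delimit cycles, each beginning in the swing phase. The first and
#' last `edge_s` seconds are excluded (filter edge effects), cycles shorter
#' than 0.25 s are impossible at these stride frequencies and are dropped, and
#' cycles longer than `max_cycle_frac` times the period hint (e.g. spanning a
#' silent gap between movement bouts) are dropped as well.
#'
#' @param gyr_sagittal Sign-normalised sagittal angular velocity (deg/s).
#' @param period_hint Cycle period from [estimate_cycle_period()], seconds.
#' @param spec A [filter_spec()]; its `rate_hz` is taken as the sampling rate.
#' @param min_sep_frac,prom_frac,edge_s,max_cycle_frac Detection parameters.
#' @return Tibble of cycle boundaries `i_start`, `i_end` (1-based sample
#'   indices, half-open `[i_start, i_end)`).
#' @export
segment_cycles <- function(gyr_sagittal, period_hint, spec = filter_spec(),
                           min_sep_frac = 0.7, prom_frac = 0.3,
                           edge_s = 0.5, max_cycle_frac = 1.8) {
  rate <- spec$rate_hz
  y <- lowpass(gyr_sagittal, spec)
  n <- length(y)
  edge <- round(edge_s * rate)
  # prominence floor: 0.3x the 95th-percentile amplitude, itself floored at
  # 5% of the maximum so that numerically quiet traces do not admit ripples
  amp <- max(quantile(abs(y), 0.95, names = FALSE), 0.05 * max(abs(y)))
  pk <- find_peaks(
    y,
    min_separation = min_sep_frac * period_hint * rate,
    min_prominence = prom_frac * amp)
  pk <- pk[pk$index > edge & pk$index <= n - edge, ]
  if (nrow(pk) < 3) {
    abort("fewer than 3 swing peaks found; not enough strides to segment",
          class = "eqg_insufficient_strides_error")
  }
  b <- tibble(i_start = head(pk$index, -1), i_end = tail(pk$index, -1))
  len <- b$i_end - b$i_start
  b[len >= 0.25 * rate & len <= max_cycle_frac * period_hint * rate, ]
}

#' Sign-normalised sagittal angular velocity for a limb recording
#'
#' The sagittal-plane rotation (protraction/retraction) is the gyroscope
#' component about the mediolateral axis; with the sensor z-axis pointing
#' medially this is `gyr_z`, and right-limb signals are negated so that
#' protraction is positive on both body sides.
#'
#' @param rec An [imu_recording()] from a limb site.
#' @return Numeric vector (deg/s).
#' @export
sagittal_angular_velocity <- function(rec) {
  site <- rec_site(rec)
  if (!site %in% limb_sites) {
    abort("sagittal angular velocity is defined for limb sensors only",
          class = "eqg_data_error")
  }
  sgn <- if (site %in% c("RF", "RH")) -1 else 1
  sgn * rec$gyr_z
}

#' Detect hoof-on and hoof-off within segmented cycles
#'
#' Within each cycle, candidate events are local maxima of the acceleration
#' magnitude exceeding `max(min_peak_g, cycle baseline + mad_k * MAD)` with a
#' minimum separation of `refractory_ms`. Hoof-on is the first candidate
#' (initial ground contact); hoof-off is the most prominent candidate after
#' it. The peak impact limb load (PILL) is read from `acc_raw` -- by default
#' the unfiltered magnitude, so the load is not attenuated by the detection
#' filter -- within `pill_window_ms` of the detected hoof-on: with five or
#' more strides the trial's average normalised impact-pulse shape is formed
#' over those windows and each stride's amplitude is least-squares fitted
#' against it (exact for noiseless pulses, and averaging down the per-sample
#' noise otherwise); with fewer strides the window maximum is used. Cycles
#' with fewer than two candidates are dropped and counted.
#'
#' @param acc_mag Acceleration magnitude used for peak picking (g); typically
#'   the 20 Hz low-passed magnitude.
#' @param boundaries Cycle boundaries from [segment_cycles()].
#' @param rate_hz Sampling rate.
#' @param acc_raw Unfiltered magnitude for the PILL readout (defaults to
#'   `acc_mag`).
#' @param t Optional time vector; defaults to `(index - 1) / rate_hz`.
#' @param min_peak_g Absolute floor for impact candidates (g).
#' @param mad_k Robust threshold multiplier over the cycle baseline.
#' @param refractory_ms Minimum separation between candidates (ms).
#' @param pill_window_ms Half-window for the raw-magnitude PILL readout (ms).
#' @param shape Optional impact-pulse template for the PILL readout (e.g.
#'   pooled over a trial's limbs, as [analyze_trial()] does); by default it
#'   is built from this signal's own strides.
#' @return List with `cycles` (tibble: `i_start`, `i_end`, `cycle_start_s`,
#'   `hoof_on_s`, `hoof_off_s`, `cycle_end_s`, `pill_g`), `dropped` (number
#'   of cycles without two usable events) and `pill_input` (the readout's
#'   windows, for template pooling across limbs).
#' @export
detect_hoof_events <- function(acc_mag, boundaries, rate_hz = 120,
                               acc_raw = acc_mag, t = NULL,
                               min_peak_g = 2, mad_k = 4,
                               refractory_ms = 50, pill_window_ms = 25,
                               shape = NULL) {
  if (is.null(t)) t <- (seq_along(acc_mag) - 1) / rate_hz
  refr <- refractory_ms / 1000 * rate_hz
  win <- round(pill_window_ms / 1000 * rate_hz)
  rows <- list()
  dropped <- 0L
  for (k in seq_len(nrow(boundaries))) {
    i0 <- boundaries$i_start[k]; i1 <- boundaries$i_end[k]
    seg <- acc_mag[i0:(i1 - 1)]
    thr <- max(min_peak_g, median(seg) + mad_k * mad(seg))
    pk <- find_peaks(seg, min_separation = refr, min_height = thr)
    if (nrow(pk) < 2) { dropped <- dropped + 1L; next }
    on_local <- pk$index[1]
    after <- pk[pk$index > on_local, ]
    off_local <- after$index[which.max(after$prominence)]
    i_on <- i0 + on_local - 1L
    i_off <- i0 + off_local - 1L
    rows[[length(rows) + 1L]] <- tibble(
      i_start = i0, i_end = i1, i_on = i_on,
      cycle_start_s = t[i0], hoof_on_s = t[i_on], hoof_off_s = t[i_off],
      cycle_end_s = t[i1],
      baseline_g = median(acc_raw[i0:(i1 - 1)]))
  }
  if (length(rows) == 0) {
    abort(sprintf("hoof-event detection failed in all %d cycles", dropped),
          class = "eqg_detection_failure_error")
  }
  cycles <- bind_rows(rows)
  cycles$pill_g <- pill_amplitude(acc_raw, cycles$i_on, cycles$baseline_g,
                                  win, shape = shape)
  bad <- cycles$pill_g <= 1
  dropped <- dropped + sum(bad)
  cycles <- cycles[!bad, ]
  if (nrow(cycles) == 0) {
    abort(sprintf("hoof-event detection failed in all %d cycles", dropped),
          class = "eqg_detection_failure_error")
  }
  pill_input <- list(acc_raw = acc_raw, i_on = cycles$i_on,
                     baseline = cycles$baseline_g, win = win)
  cycles <- cycles[, !(names(cycles) %in% c("i_on", "baseline_g"))]
  list(cycles = cycles, dropped = dropped, pill_input = pill_input)
}

# Baseline-removed windows of the raw magnitude around detected hoof-on
# peaks, re-centred on their local maximum.
pill_windows <- function(acc_raw, i_on, baseline, win) {
  n <- length(acc_raw)
  centers <- vapply(i_on, function(i) {
    j <- max(1, i - 1):min(n, i + 1)
    j[which.max(acc_raw[j])]
  }, integer(1))
  ok <- centers - win >= 1 & centers + win <= n
  w <- t(vapply(centers[ok], function(c) acc_raw[(c - win):(c + win)],
                numeric(2 * win + 1)))
  list(w = w - baseline[ok], ok = ok,
       peak_val = acc_raw[centers], amp0 = acc_raw[centers[ok]] - baseline[ok])
}

# PILL readout: with >= 5 usable strides, each stride's amplitude is the
# least-squares projection onto the average baseline-removed, peak-normalised
# impact-pulse shape (`shape`; built from this limb's own windows when not
# supplied). Exact for noiseless pulses, and averaging down per-sample noise
# otherwise. Falls back to the re-centred window maximum when too few strides
# support a template.
pill_amplitude <- function(acc_raw, i_on, baseline, win, shape = NULL) {
  pw <- pill_windows(acc_raw, i_on, baseline, win)
  out <- pw$peak_val
  if (sum(pw$ok) < 5) {
    n <- length(acc_raw)
    return(vapply(seq_along(i_on), function(k) {
      j <- max(1, i_on[k] - win):min(n, i_on[k] + win)
      max(acc_raw[j])
    }, numeric(1)))
  }
  if (is.null(shape)) shape <- pill_shape(list(pw))
  fit <- as.numeric(pw$w %*% shape) / sum(shape^2)
  out[pw$ok] <- baseline[pw$ok] + fit
  out
}

# Average normalised impact-pulse shape over one or more window sets (e.g.
# pooled across the four limbs of a trial, whose transients share their
# shape; pooling makes the template's scale error common to all limbs, so it
# cancels in the asymmetry ratios).
pill_shape <- function(window_sets) {
  norm_w <- do.call(rbind, lapply(window_sets, function(pw) pw$w / pw$amp0))
  shape <- pmax(colMeans(norm_w), 0)
  shape / max(shape)
}
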