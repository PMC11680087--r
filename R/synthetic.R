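# Synthetic five-sensor gait trials (walk, trot, left/right-lead canter) with
# per-stride ground truth, used to validate every pipeline stage.

#' Footfall template of a gait
#'
#' Hoof-on phase offsets (fraction of the stride) per limb. Walk is four-beat
#' with the lateral sequence LH, LF, RH, RF at quarter-stride spacing; trot is
#' two-beat with synchronous diagonal pairs (LF+RH, RF+LH); canter is
#' three-beat: trailing hind first, the diagonal pair together, then the
#' leading fore (the phase values 0 / 0.30 / 0.45 are simulator conventions,
#' not claims about real horses).
#'
#' @param gait One of [gait_levels].
#' @return List with `phases` (named numeric, hoof-on phase in `[0, 1)`) and
#'   `beats`.
#' @export
gait_template <- function(gait) {
  gait <- match.arg(gait, gait_levels)
  switch(gait,
    walk = list(phases = c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75), beats = 4L),
    trot = list(phases = c(LF = 0, RH = 0, RF = 0.5, LH = 0.5), beats = 2L),
    canter_right = list(phases = c(LH = 0, RH = 0.3, LF = 0.3, RF = 0.45),
                        beats = 3L),
    canter_left = list(phases = c(RH = 0, LH = 0.3, RF = 0.3, LF = 0.45),
                       beats = 3L))
}

# Cohort-scale defaults per base gait: stride frequency (Hz), duty factor
# (stance x frequency) and mean PILL (g).
gait_defaults <- function(gait_base) {
  switch(gait_base,
    walk = list(stride_freq_hz = 0.83, duty_factor = 0.62889,
                impact_peak_g = 6.55),
    trot = list(stride_freq_hz = 1.30, duty_factor = 0.40713,
                impact_peak_g = 9.77),
    canter = list(stride_freq_hz = 1.61, duty_factor = 0.41934,
                  impact_peak_g = 14.03))
}

base_gait <- function(gait) if (grepl("^canter", gait)) "canter" else gait

#' Specification of a synthetic trial
#'
#' Defaults for stride frequency, duty factor and impact peak follow the
#' cohort means per gait (walk 0.83 Hz / 6.55 g, trot 1.30 Hz / 9.77 g,
#' canter 1.61 Hz / 14.03 g; duty factor = stance duration x frequency).
#' `duty_factor` and `impact_peak_g` may be scalars or named per-limb vectors.
#'
#' @param gait One of [gait_levels].
#' @param stride_freq_hz Stride frequency (0.4-2.5 Hz).
#' @param duty_factor Stance fraction of the stride, per limb or scalar.
#' @param impact_peak_g Hoof-on magnitude peak (g), per limb or scalar (> 2).
#' @param hoof_off_fraction Hoof-off peak as a fraction of the hoof-on peak.
#' @param pulse_sigma_s Gaussian impact pulse width (s).
#' @param gyr_amp_dps Swing-lobe amplitude of the sagittal angular velocity.
#' @param pitch_mean_deg,pitch_amp_deg Limb pitch oscillation (degrees).
#' @param noise_sd_g,noise_sd_dps Additive white noise SD per axis.
#' @param pitch_noise_sd_deg Noise SD on the orientation channel.
#' @param duration_s Trial length (default 40 s).
#' @param rate_hz Sampling rate (default 120 Hz).
#' @param seed RNG seed; identical seeds give identical trials.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(gait = "walk", stride_freq_hz = NULL,
                           duty_factor = NULL, impact_peak_g = NULL,
                           hoof_off_fraction = 0.55, pulse_sigma_s = 0.015,
                           gyr_amp_dps = 300, pitch_mean_deg = 60,
                           pitch_amp_deg = 10, noise_sd_g = 0.3,
                           noise_sd_dps = 15, pitch_noise_sd_deg = 0.5,
                           duration_s = 40, rate_hz = 120, seed = 1) {
  gait <- match.arg(gait, gait_levels)
  def <- gait_defaults(base_gait(gait))
  stride_freq_hz <- stride_freq_hz %||% def$stride_freq_hz
  duty_factor <- duty_factor %||% def$duty_factor
  impact_peak_g <- impact_peak_g %||% def$impact_peak_g
  per_limb <- function(x, what) {
    if (length(x) == 1) x <- setNames(rep(x, 4), limb_sites)
    if (!all(limb_sites %in% names(x))) {
      abort(paste0(what, " must be a scalar or named per limb"),
            class = "eqg_spec_error")
    }
    x[limb_sites]
  }
  duty_factor <- per_limb(duty_factor, "duty_factor")
  impact_peak_g <- per_limb(impact_peak_g, "impact_peak_g")
  if (stride_freq_hz < 0.4 || stride_freq_hz > 2.5) {
    abort("stride_freq_hz must lie in [0.4, 2.5]", class = "eqg_spec_error")
  }
  if (any(duty_factor <= 0.05 | duty_factor >= 0.95)) {
    abort("duty_factor must lie in (0.05, 0.95)", class = "eqg_spec_error")
  }
  if (any(impact_peak_g <= 2)) {
    abort("impact peaks must exceed 2 g", class = "eqg_spec_error")
  }
  t_stride <- 1 / stride_freq_hz
  stance <- duty_factor * t_stride
  swing <- (1 - duty_factor) * t_stride
  if (any(stance < 4 * pulse_sigma_s) || any(swing < 4 * pulse_sigma_s)) {
    abort("impact pulses overlap: duty factor infeasible at this stride frequency",
          class = "eqg_spec_error")
  }
  structure(list(
    gait = gait, stride_freq_hz = stride_freq_hz, duty_factor = duty_factor,
    impact_peak_g = impact_peak_g, hoof_off_fraction = hoof_off_fraction,
    pulse_sigma_s = pulse_sigma_s, gyr_amp_dps = gyr_amp_dps,
    pitch_mean_deg = pitch_mean_deg, pitch_amp_deg = pitch_amp_deg,
    noise_sd_g = noise_sd_g, noise_sd_dps = noise_sd_dps,
    pitch_noise_sd_deg = pitch_noise_sd_deg,
    duration_s = duration_s, rate_hz = rate_hz, seed = seed),
    class = "synthetic_spec")
}

gauss_pulse <- function(t, centers, amps, sigma) {
  out <- numeric(length(t))
  for (i in seq_along(centers)) {
    lo <- centers[i] - 5 * sigma; hi <- centers[i] + 5 * sigma
    idx <- which(t >= lo & t <= hi)
    out[idx] <- out[idx] + amps[i] * exp(-(t[idx] - centers[i])^2 / (2 * sigma^2))
  }
  out
}

# Per-limb event schedule: hoof-on at (k + phase) * T, stance dT. An event is
# kept when its swing peak clears the 0.5 s filter-edge exclusion and its
# stance (plus pulse support) fits inside the trial.
limb_events <- function(spec, limb) {
  tpl <- gait_template(spec$gait)
  t_stride <- 1 / spec$stride_freq_hz
  d <- spec$duty_factor[[limb]]
  half_swing <- (1 - d) * t_stride / 2
  k <- 0:ceiling(spec$duration_s / t_stride)
  on <- (k + tpl$phases[[limb]]) * t_stride
  keep <- (on - half_swing) >= 0.52 &
    (on + d * t_stride + 4 * spec$pulse_sigma_s) <= spec$duration_s
  on <- on[keep]
  # event times are quantised to the sampling grid so the imposed peak loads
  # are realised exactly in the sampled signal
  on <- round(on * spec$rate_hz) / spec$rate_hz
  off <- round((on + d * t_stride) * spec$rate_hz) / spec$rate_hz
  peak <- spec$impact_peak_g[[limb]]
  tibble(limb = limb, stride_idx = seq_along(on),
         t_on_s = on, t_off_s = off,
         t_swing_peak_s = on - half_swing,
         peak_g = peak)
}

#' Noiseless acceleration-magnitude trace of one limb
#'
#' Baseline 1 g plus a Gaussian pulse peaking at the specified impact load at
#' each hoof-on and a smaller pulse (`hoof_off_fraction` of the impact peak)
#' at each hoof-off.
#' @noRd
limb_magnitude <- function(t, events, spec) {
  a_on <- events$peak_g - 1
  a_off <- spec$hoof_off_fraction * events$peak_g - 1
  1 +
    gauss_pulse(t, events$t_on_s, a_on, spec$pulse_sigma_s) +
    gauss_pulse(t, events$t_off_s, a_off, spec$pulse_sigma_s)
}

#' Generate one synthetic five-sensor trial with ground truth
#'
#' Per limb, the acceleration magnitude is a 1 g baseline with Gaussian
#' impact pulses (width `pulse_sigma_s`) at each hoof-on (peaking at the
#' specified load) and smaller pulses at each hoof-off; the tri-axial
#' components place the pulse and gravity along the sensor x-axis so the
#' Euclidean norm equals the target magnitude. The sagittal angular velocity
#' is one positive half-sine lobe per swing phase (negated on right limbs to
#' mimic the medially pointing z-axis); the orientation channel carries a
#' pitch sinusoid at the stride frequency. The trunk sensor gets a vertical
#' oscillation at two per stride in trot and one per stride otherwise. White
#' noise is added per axis.
#'
#' @param spec A [synthetic_spec()].
#' @param rein Rein direction for the metadata; defaults to the canter lead
#'   or `"left"`.
#' @param horse_id Identifier for the metadata.
#' @return List with `trial` (a [trial_recording()]) and `truth` (list:
#'   `events` tibble `limb, stride_idx, t_on_s, t_off_s, t_swing_peak_s,
#'   peak_g`, and `period_s`).
#' @export
generate_trial <- function(spec, rein = NULL, horse_id = "SYN") {
  stopifnot(inherits(spec, "synthetic_spec"))
  rein <- rein %||% switch(spec$gait, canter_left = "left",
                           canter_right = "right", "left")
  set.seed(spec$seed)
  rate <- spec$rate_hz
  t <- seq(0, spec$duration_s - 1 / rate, by = 1 / rate)
  n <- length(t)
  t_stride <- 1 / spec$stride_freq_hz
  recs <- list()
  truth <- list()
  for (limb in limb_sites) {
    ev <- limb_events(spec, limb)
    truth[[limb]] <- ev
    mag <- limb_magnitude(t, ev, spec)
    gyr <- numeric(n)
    d <- spec$duty_factor[[limb]]
    swing_dur <- (1 - d) * t_stride
    for (i in seq_len(nrow(ev))) {
      s0 <- ev$t_on_s[i] - swing_dur
      idx <- which(t >= s0 & t <= ev$t_on_s[i])
      gyr[idx] <- spec$gyr_amp_dps * sin(pi * (t[idx] - s0) / swing_dur)
    }
    # closing swing lobe of the stride after the last hoof-on, so that the
    # last recorded stride's cycle can be delimited
    if (nrow(ev) > 0) {
      s0 <- max(ev$t_on_s) + t_stride - swing_dur
      if (s0 + swing_dur / 2 <= spec$duration_s - 0.52) {
        idx <- which(t >= s0 & t <= s0 + swing_dur)
        gyr[idx] <- spec$gyr_amp_dps * sin(pi * (t[idx] - s0) / swing_dur)
      }
    }
    if (limb %in% c("RF", "RH")) gyr <- -gyr
    phase0 <- gait_template(spec$gait)$phases[[limb]]
    pitch <- spec$pitch_mean_deg +
      spec$pitch_amp_deg * sin(2 * pi * spec$stride_freq_hz * (t - phase0 * t_stride))
    df <- tibble(
      time_s = t,
      acc_x = mag + rnorm(n, 0, spec$noise_sd_g),
      acc_y = rnorm(n, 0, spec$noise_sd_g),
      acc_z = rnorm(n, 0, spec$noise_sd_g),
      gyr_x = rnorm(n, 0, spec$noise_sd_dps),
      gyr_y = rnorm(n, 0, spec$noise_sd_dps),
      gyr_z = gyr + rnorm(n, 0, spec$noise_sd_dps),
      roll_deg = rnorm(n, 0, spec$pitch_noise_sd_deg),
      pitch_deg = pmin(90, pmax(-90, pitch + rnorm(n, 0, spec$pitch_noise_sd_deg))),
      yaw_deg = rnorm(n, 0, spec$pitch_noise_sd_deg))
    recs[[limb]] <- imu_recording(df, site = limb, rate_hz = rate)
  }
  # trunk: gravity along z, vertical bounce once (or twice, in trot) per stride
  bounce_per_stride <- if (base_gait(spec$gait) == "trot") 2 else 1
  trunk_pitch <- 5 * sin(2 * pi * spec$stride_freq_hz * t)
  trunk <- tibble(
    time_s = t,
    acc_x = rnorm(n, 0, spec$noise_sd_g),
    acc_y = rnorm(n, 0, spec$noise_sd_g),
    acc_z = 1 + 0.4 * sin(2 * pi * bounce_per_stride * spec$stride_freq_hz * t) +
      rnorm(n, 0, spec$noise_sd_g),
    gyr_x = rnorm(n, 0, spec$noise_sd_dps),
    gyr_y = rnorm(n, 0, spec$noise_sd_dps),
    gyr_z = rnorm(n, 0, spec$noise_sd_dps),
    roll_deg = rnorm(n, 0, spec$pitch_noise_sd_deg),
    pitch_deg = pmin(90, pmax(-90, trunk_pitch + rnorm(n, 0, spec$pitch_noise_sd_deg))),
    yaw_deg = rnorm(n, 0, spec$pitch_noise_sd_deg))
  recs[["TRUNK"]] <- imu_recording(trunk, site = "TRUNK", rate_hz = rate)
  meta <- trial_meta(horse_id, spec$gait, rein,
                     duration_s = spec$duration_s, surface = "synthetic")
  list(trial = trial_recording(recs, meta),
       truth = list(events = bind_rows(truth), period_s = t_stride))
}

#' Per-axis noise SD giving a requested power signal-to-noise ratio
#'
#' SNR is defined as the time-averaged power of the noiseless magnitude
#' signal above its 1 g baseline divided by the per-axis noise power; the
#' returned SD is the limb-mean RMS of the pulse train divided by sqrt(SNR).
#'
#' @param spec A [synthetic_spec()].
#' @param snr Target power SNR (> 0).
#' @return Noise SD in g.
#' @export
noise_sd_for_snr <- function(spec, snr) {
  stopifnot(snr > 0)
  rate <- spec$rate_hz
  t <- seq(0, spec$duration_s - 1 / rate, by = 1 / rate)
  rms <- vapply(limb_sites, function(limb) {
    ev <- limb_events(spec, limb)
    sqrt(mean((limb_magnitude(t, ev, spec) - 1)^2))
  }, numeric(1))
  mean(rms) / sqrt(snr)
}

#' Generate a cohort manifest of synthetic trials
#'
#' Reproduces the study layout: per horse and gait, `per_gait_trials` trials
#' balanced across rein direction (canter trials on the left rein are ridden
#' in left-lead canter, right-rein trials in right-lead). Horse-specific
#' longitudinal and lateral asymmetry offsets are drawn once per horse from
#' normal distributions and imposed by scaling the per-limb impact peaks
#' around the gait's mean load, so the imposed indices are exact ground
#' truth. Trials are materialised lazily with [cohort_trial()].
#'
#' @param n_horses Number of horses (default 20; >= 2).
#' @param per_gait_trials Trials per horse and gait (default 4, half per rein).
#' @param gaits Base gaits to include.
#' @param longai_mean Named per-gait mean of the horse LongAI offsets (%).
#' @param longai_sd,latai_sd SD of the horse-level LongAI / LatAI offsets (%).
#' @param duration_s,rate_hz,noise_sd_g,noise_sd_dps Trial-level settings.
#' @param seed Cohort seed; per-trial seeds are drawn from it.
#' @return Tibble manifest, one row per trial, carrying the metadata, the
#'   per-limb impact peaks, the true asymmetry indices and the per-trial seed.
#' @export
generate_cohort <- function(n_horses = 20, per_gait_trials = 4,
                            gaits = c("walk", "trot", "canter"),
                            longai_mean = c(walk = -6.24, trot = -11.53,
                                            canter = -0.72),
                            longai_sd = 10, latai_sd = 5,
                            duration_s = 40, rate_hz = 120,
                            noise_sd_g = 0.3, noise_sd_dps = 15, seed = 1) {
  if (n_horses < 2) abort("need at least 2 horses", class = "eqg_spec_error")
  if (per_gait_trials %% 2 != 0) {
    abort("per_gait_trials must be even to balance rein directions",
          class = "eqg_spec_error")
  }
  set.seed(seed)
  rows <- list()
  for (h in seq_len(n_horses)) {
    horse <- sprintf("H%02d", h)
    horse_long <- rnorm(1, 0, longai_sd)
    horse_lat_fore <- rnorm(1, 0, latai_sd)
    horse_lat_hind <- rnorm(1, 0, latai_sd)
    for (gait_base in gaits) {
      def <- gait_defaults(gait_base)
      long_ai <- horse_long + longai_mean[[gait_base]]
      p <- def$impact_peak_g
      f <- p * (1 + long_ai / 200); hh <- p * (1 - long_ai / 200)
      peaks <- c(LF = f * (1 + horse_lat_fore / 200),
                 RF = f * (1 - horse_lat_fore / 200),
                 LH = hh * (1 + horse_lat_hind / 200),
                 RH = hh * (1 - horse_lat_hind / 200))
      for (k in seq_len(per_gait_trials)) {
        rein <- if (k <= per_gait_trials / 2) "left" else "right"
        gait <- if (gait_base == "canter") paste0("canter_", rein) else gait_base
        rows[[length(rows) + 1L]] <- tibble(
          horse_id = horse, gait = gait, gait_base = gait_base, rein = rein,
          trial = k, seed = sample.int(.Machine$integer.max - 1, 1),
          stride_freq_hz = def$stride_freq_hz,
          duty_factor = def$duty_factor,
          peak_lf_g = peaks[["LF"]], peak_rf_g = peaks[["RF"]],
          peak_lh_g = peaks[["LH"]], peak_rh_g = peaks[["RH"]],
          true_long_ai_pct = long_asymmetry_index(f, hh),
          true_lat_ai_fore_pct = lat_asymmetry_index(peaks[["LF"]], peaks[["RF"]]),
          true_lat_ai_hind_pct = lat_asymmetry_index(peaks[["LH"]], peaks[["RH"]]),
          duration_s = duration_s, rate_hz = rate_hz,
          noise_sd_g = noise_sd_g, noise_sd_dps = noise_sd_dps)
      }
    }
  }
  bind_rows(rows)
}

#' Materialise one cohort trial
#'
#' @param row One row of a [generate_cohort()] manifest.
#' @return As [generate_trial()].
#' @export
cohort_trial <- function(row) {
  spec <- synthetic_spec(
    gait = row$gait, stride_freq_hz = row$stride_freq_hz,
    duty_factor = row$duty_factor,
    impact_peak_g = c(LF = row$peak_lf_g, RF = row$peak_rf_g,
                      LH = row$peak_lh_g, RH = row$peak_rh_g),
    noise_sd_g = row$noise_sd_g, noise_sd_dps = row$noise_sd_dps,
    duration_s = row$duration_s, rate_hz = row$rate_hz, seed = row$seed)
  generate_trial(spec, rein = row$rein, horse_id = row$horse_id)
}

#' Write ground-truth events to CSV
#'
#' Columns `limb, stride_idx, t_on_s, t_off_s, peak_g`.
#' @param truth Ground truth from [generate_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth$events[, c("limb", "stride_idx", "t_on_s",
                                    "t_off_s", "peak_g")],
                   path, progress = FALSE)
  invisible(path)
}
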