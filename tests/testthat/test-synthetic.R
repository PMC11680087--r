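test_that("identical seeds give byte-identical trials; seeds only differing in noise share timing", {
  spec <- synthetic_spec("trot", duration_s = 8, seed = 51)
  a <- generate_trial(spec)
  b <- generate_trial(spec)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(a$trial$recordings$LH, p1)
  write_recording(b$trial$recordings$LH, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a$truth$events, b$truth$events)

  spec2 <- synthetic_spec("trot", duration_s = 8, seed = 52)
  c2 <- generate_trial(spec2)
  expect_identical(a$truth$events, c2$truth$events)
  expect_false(identical(a$trial$recordings$LH$acc_y,
                         c2$trial$recordings$LH$acc_y))
})

test_that("footfall templates carry the gait structure into the ground truth", {
  walk <- gait_template("walk")
  expect_identical(walk$beats, 4L)
  expect_identical(length(unique(walk$phases)), 4L)
  expect_equal(sort(unname(walk$phases)), c(0, 0.25, 0.5, 0.75))

  trot <- generate_trial(synthetic_spec("trot", duration_s = 10, seed = 53))
  ev <- trot$truth$events
  lf <- ev$t_on_s[ev$limb == "LF"]; rh <- ev$t_on_s[ev$limb == "RH"]
  n <- min(length(lf), length(rh))
  expect_true(all(abs(lf[1:n] - rh[1:n]) < 0.001))

  cr <- gait_template("canter_right")
  expect_identical(cr$beats, 3L)
  expect_identical(length(unique(cr$phases)), 3L)
  # right lead: trailing left hind starts, leading right fore lands last
  expect_equal(unname(cr$phases["LH"]), 0)
  expect_gt(cr$phases[["RF"]], max(cr$phases[c("LH", "RH", "LF")]))
  cl <- gait_template("canter_left")
  expect_equal(unname(cl$phases["RH"]), 0)
  expect_gt(cl$phases[["LF"]], max(cl$phases[c("LH", "RH", "RF")]))
})

test_that("a 40 s walk at 0.83 Hz carries 33 +/- 1 strides per limb", {
  sim <- generate_trial(synthetic_spec("walk", seed = 54))
  counts <- table(sim$truth$events$limb)
  expect_true(all(counts >= 32 & counts <= 34))
  expect_equal(sim$truth$period_s, 1 / 0.83)
  # events ordered and inside the trial; stance inside the stride
  ev <- sim$truth$events
  expect_true(all(ev$t_off_s > ev$t_on_s))
  expect_true(all(ev$t_off_s - ev$t_on_s < sim$truth$period_s))
  expect_true(all(ev$t_on_s > 0 & ev$t_off_s < 40))
  expect_lte(max(counts) - min(counts), 1)
})

test_that("noiseless signals and ground truth are mutually consistent", {
  spec <- synthetic_spec("canter_right", noise_sd_g = 0, noise_sd_dps = 0,
                         pitch_noise_sd_deg = 0, duration_s = 15, seed = 55)
  sim <- generate_trial(spec)
  for (l in limb_sites) {
    rec <- sim$trial$recordings[[l]]
    mag <- acceleration_magnitude(rec)
    ev <- sim$truth$events[sim$truth$events$limb == l, ]
    for (i in seq_len(nrow(ev))) {
      win <- which(abs(rec$time_s - ev$t_on_s[i]) <= 0.025)
      expect_lt(abs(max(mag[win]) - ev$peak_g[i]) / ev$peak_g[i], 0.01)
    }
  }
})

test_that("infeasible specifications are rejected", {
  expect_error(synthetic_spec("walk", stride_freq_hz = 3),
               class = "eqg_spec_error")
  expect_error(synthetic_spec("walk", duty_factor = 0.99),
               class = "eqg_spec_error")
  expect_error(synthetic_spec("walk", impact_peak_g = 1.5),
               class = "eqg_spec_error")
  # pulses overlap: tiny swing at high frequency
  expect_error(synthetic_spec("trot", stride_freq_hz = 2.4,
                              duty_factor = 0.94),
               class = "eqg_spec_error")
})

test_that("cohort manifests reproduce the study layout with exact imposed asymmetries", {
  man <- generate_cohort(n_horses = 20, per_gait_trials = 4, seed = 56)
  expect_identical(nrow(man), 240L)
  expect_true(all(table(man$gait_base) == 80))
  per <- dplyr::count(man, horse_id, gait_base, rein)
  expect_true(all(per$n == 2))
  expect_true(all(man$gait[man$gait_base == "canter" & man$rein == "left"] ==
                    "canter_left"))
  # the recorded true indices match the imposed per-limb peaks
  expect_equal(man$true_long_ai_pct,
               long_asymmetry_index((man$peak_lf_g + man$peak_rf_g) / 2,
                                    (man$peak_lh_g + man$peak_rh_g) / 2),
               tolerance = 1e-9)
  expect_equal(man$true_lat_ai_fore_pct,
               lat_asymmetry_index(man$peak_lf_g, man$peak_rf_g),
               tolerance = 1e-9)

  zero <- generate_cohort(n_horses = 4, longai_sd = 0, latai_sd = 0,
                          longai_mean = c(walk = 0, trot = 0, canter = 0),
                          seed = 57)
  expect_equal(mean(zero$true_long_ai_pct), 0, tolerance = 1e-9)
  expect_error(generate_cohort(n_horses = 1), class = "eqg_spec_error")
  expect_error(generate_cohort(per_gait_trials = 3), class = "eqg_spec_error")
})

test_that("noise_sd_for_snr scales inversely with the square root of the SNR", {
  spec <- synthetic_spec("walk", duration_s = 10, seed = 58)
  s10 <- noise_sd_for_snr(spec, 10)
  s40 <- noise_sd_for_snr(spec, 40)
  expect_equal(s10 / s40, 2, tolerance = 1e-9)
  expect_gt(s10, 0)
})
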