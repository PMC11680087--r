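test_that("cycle period is recovered from clean and noisy pitch oscillations", {
  rate <- 120
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  pitch <- 60 + 10 * sin(2 * pi * t / 0.78)
  expect_equal(estimate_cycle_period(pitch, rate), 0.78, tolerance = 0.02 / 0.78)

  # power SNR 5: noise SD = amplitude / sqrt(2 * 5)
  set.seed(21)
  noisy <- pitch + rnorm(length(t), 0, 10 / sqrt(10))
  expect_equal(estimate_cycle_period(noisy, rate), 0.78, tolerance = 0.05)

  expect_error(estimate_cycle_period(rep(60, length(t)), rate),
               class = "eqg_no_gait_error")
  expect_error(estimate_cycle_period(pitch[1:400], rate),
               class = "eqg_data_error")
})

test_that("swing-peak lobes delimit cycles: n peaks give n - 1 cycles", {
  lt <- lobe_train(centers = 1 + 0:32 * 1.17, duration_s = 40)
  spec <- filter_spec(rate_hz = 120)
  b <- segment_cycles(lt$y, period_hint = 1.17, spec = spec)
  expect_identical(nrow(b), 32L)
  # boundaries sit on the imposed lobe centres
  expect_true(all(abs(b$i_start - lt$centers_idx[1:32]) <= 2))
  expect_true(all(abs(b$i_end - lt$centers_idx[2:33]) <= 2))
  # cycles are disjoint and time-ordered
  expect_true(all(diff(b$i_start) > 0))
  expect_true(all(b$i_end[-nrow(b)] == b$i_start[-1]))
})

test_that("segmentation tolerates jittered spacing and never spans silent gaps", {
  set.seed(22)
  period <- 1.0
  centers <- 1 + cumsum(period * runif(30, 0.95, 1.05))
  lt <- lobe_train(centers, duration_s = 40)
  b <- segment_cycles(lt$y, period_hint = period, spec = filter_spec())
  truth_idx <- lt$centers_idx
  expect_identical(nrow(b), length(centers) - 1L)
  expect_true(all(abs(b$i_start - truth_idx[-length(truth_idx)]) <= 2))

  # two bouts separated by 2 s of zeros: no cycle crosses the gap
  rate <- 120
  bout1 <- 1 + 0:13 * period
  bout2 <- max(bout1) + 2 + period + 0:13 * period
  lt2 <- lobe_train(c(bout1, bout2), duration_s = 40)
  b2 <- segment_cycles(lt2$y, period_hint = period, spec = filter_spec())
  gap_start <- (max(bout1) + 0.3) * rate
  gap_end <- (max(bout1) + 2 + period - 0.5) * rate
  spans_gap <- b2$i_start < gap_start & b2$i_end > gap_end
  expect_false(any(spans_gap))
  expect_true(all((b2$i_end - b2$i_start) <= 1.8 * period * rate))

  expect_error(segment_cycles(lobe_train(c(2, 3))$y, period_hint = 1,
                              spec = filter_spec()),
               class = "eqg_insufficient_strides_error")
})

test_that("two impact pulses within a cycle give hoof-on, hoof-off and the stance between them", {
  rate <- 120
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  # one cycle from 0.5 s to 2.0 s: hoof-on pulse 9 g at 0.8 s, hoof-off 5 g at 1.1 s
  y <- pulse_train(t, centers = c(0.8, 1.1), peaks = c(9, 5))
  b <- tibble::tibble(i_start = round(0.5 * rate) + 1L,
                      i_end = round(2.0 * rate) + 1L)
  det <- detect_hoof_events(y, b, rate_hz = rate)
  expect_identical(det$dropped, 0L)
  stance_ms <- 1000 * (det$cycles$hoof_off_s - det$cycles$hoof_on_s)
  expect_lt(abs(stance_ms - 300), 17)
  expect_equal(det$cycles$pill_g, 9, tolerance = 0.02)
})

test_that("cycles with fewer than two candidates are dropped and counted", {
  rate <- 120
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  y <- pulse_train(t, centers = c(1.0, 1.3, 3.2), peaks = c(9, 5, 8))
  b <- tibble::tibble(i_start = c(61L, 301L), i_end = c(301L, 541L))
  det <- detect_hoof_events(y, b, rate_hz = rate)
  expect_identical(det$dropped, 1L)
  expect_identical(nrow(det$cycles), 1L)

  # single-pulse cycles only -> detection failure carrying the drop count
  y2 <- pulse_train(t, centers = c(1.0, 3.2), peaks = c(9, 8))
  expect_error(detect_hoof_events(y2, b, rate_hz = rate),
               class = "eqg_detection_failure_error")
})

test_that("noiseless walk events are recovered to the sample and PILL to 2%", {
  spec <- synthetic_spec("walk", duration_s = 26, noise_sd_g = 0,
                         noise_sd_dps = 0, pitch_noise_sd_deg = 0, seed = 23)
  sim <- generate_trial(spec)
  res <- analyze_trial(sim$trial)
  expect_gte(min(table(sim$truth$events$limb)), 19)
  for (l in limb_sites) {
    det <- res$cycles[res$cycles$limb == l, ]
    tr <- sim$truth$events[sim$truth$events$limb == l, ]
    m <- sapply(det$hoof_on_s, function(x) min(abs(x - tr$t_on_s)))
    expect_true(all(m <= 1 / 120 + 1e-9))
    expect_true(all(abs(det$pill_g - 6.55) / 6.55 <= 0.02))
  }
})

test_that("events lie strictly inside ordered, disjoint cycles with plausible loads", {
  spec <- synthetic_spec("trot", duration_s = 20, seed = 24)
  sim <- generate_trial(spec)
  res <- analyze_trial(sim$trial)
  cyc <- res$cycles
  for (l in unique(cyc$limb)) {
    cl <- cyc[cyc$limb == l, ]
    expect_true(all(diff(cl$cycle_start_s) > 0))
    expect_true(all(cl$cycle_end_s[-nrow(cl)] <= cl$cycle_start_s[-1] + 1e-9))
  }
  expect_true(all(cyc$cycle_start_s <= cyc$hoof_on_s))
  expect_true(all(cyc$hoof_on_s < cyc$hoof_off_s))
  expect_true(all(cyc$hoof_off_s <= cyc$cycle_end_s))
  expect_true(all(cyc$pill_g > 1))
  # each limb contacts once per stride: counts differ by at most 1
  counts <- table(cyc$limb)
  expect_lte(max(counts) - min(counts), 1)
})
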