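test_that("rm_anova matches brute-force sums of squares and handles the zero-effect case", {
  # equal condition means with nonzero residual: F exactly 0
  base <- c(10, 12, 9, 14)
  dev <- rbind(c(1, -1, 0), c(-1, 1, 0), c(2, -2, 0), c(-2, 2, 0))
  m0 <- base + dev
  out0 <- tidy(rm_anova(long_table(m0), "y", "subject", "cond"))
  expect_equal(out0$statistic, 0, tolerance = 1e-12)
  expect_equal(out0$partial_eta2, 0, tolerance = 1e-12)

  set.seed(41)
  m <- matrix(rnorm(12, 10), 4, 3)
  got <- tidy(rm_anova(long_table(m), "y", "subject", "cond"))
  want <- bruteforce_rm_anova(m)
  expect_equal(got$statistic, want$F, tolerance = 1e-9)
  expect_equal(got$partial_eta2, want$partial_eta2, tolerance = 1e-9)
  expect_identical(got$df_num, 2)
  expect_identical(got$df_den, 6)
})

test_that("two-condition rm_anova F equals the paired t statistic squared", {
  set.seed(42)
  m <- matrix(rnorm(10, 5), 5, 2)
  f <- tidy(rm_anova(long_table(m), "y", "subject", "cond"))$statistic
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("a 3x-residual-SD condition effect is detected with a large partial eta squared", {
  set.seed(43)
  m <- matrix(rnorm(60, 0, 1), 20, 3) + rnorm(20, 0, 0.5) +
    rep(c(0, 3, 6), each = 20)
  dim(m) <- c(20, 3)
  out <- tidy(rm_anova(long_table(m), "y", "subject", "cond"))
  expect_lt(out$p_value, 0.001)
  expect_gt(out$partial_eta2, 0.8)
})

test_that("incomplete designs are rejected, trial replicates are averaged first", {
  d <- long_table(matrix(rnorm(12), 4, 3))
  expect_error(rm_anova(d[-1, ], "y", "subject", "cond"),
               class = "eqg_balance_error")
  # two trials per cell collapse to the cell mean
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, y = y + 1))
  got <- tidy(rm_anova(d2, "y", "subject", "cond"))
  d_mean <- dplyr::mutate(d, y = y + 0.5)
  expect_equal(got$statistic,
               tidy(rm_anova(d_mean, "y", "subject", "cond"))$statistic,
               tolerance = 1e-9)
})

test_that("two-factor within design reports main effects and the interaction", {
  set.seed(44)
  d <- expand.grid(subject = sprintf("S%d", 1:8),
                   g = c("walk", "trot", "canter"), r = c("L", "R"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$g == "canter", 2, 0)
  out <- tidy(rm_anova(d, "y", "subject", c("g", "r")))
  expect_setequal(out$effect, c("g", "r", "g:r"))
  expect_lt(out$p_value[out$effect == "g"], 0.01)
  expect_true(all(out$partial_eta2 >= 0 & out$partial_eta2 <= 1))
})

test_that("Tukey post hocs carry Cohen's d with its banded labels", {
  set.seed(45)
  a <- rnorm(200); b <- a + 1 * sqrt((var(a) + var(a + 1)) / 2)
  d <- long_table(cbind(a, b), conds = c("a", "b"))
  out <- posthoc_tukey(d, "y", "subject", "cond")
  expect_identical(nrow(out), 1L)
  expect_lt(abs(abs(out$cohen_d) - 1), 0.1)
  expect_identical(out$magnitude, "large")
  expect_lt(out$p_adj, 0.001)

  # hand check of d on a fixed toy table
  m <- matrix(c(1, 2, 3, 4, 2, 4, 5, 6, 0, 1, 1, 2), 4, 3)
  toy <- long_table(m)
  tuk <- posthoc_tukey(toy, "y", "subject", "cond")
  expect_equal(tuk$cohen_d[tuk$comparison == "b-a"],
               bruteforce_cohen_d(m[, 2], m[, 1]), tolerance = 1e-9)

  # identical conditions: d = 0 and adjusted p ~ 1
  same <- long_table(cbind(m[, 1], m[, 1]), conds = c("a", "b"))
  out0 <- posthoc_tukey(same, "y", "subject", "cond")
  expect_equal(out0$cohen_d, 0)
  expect_equal(out0$p_adj, 1)

  expect_identical(effect_size_label(c(0.1, 0.3, 0.6, -0.9)),
                   c("negligible", "small", "medium", "large"))
})

test_that("assumption checks are calibrated on null data and reject degenerate input", {
  set.seed(46)
  sw_ok <- sum(vapply(1:100, function(i) {
    assumption_checks(rnorm(500))$p_value > 0.05
  }, logical(1)))
  expect_gte(sw_ok, 90)

  lev_p <- vapply(1:300, function(i) {
    v <- rnorm(60); g <- rep(c("a", "b"), each = 30)
    tab <- assumption_checks(v, g)
    tab$p_value[tab$test == "levene"]
  }, numeric(1))
  expect_gt(stats::ks.test(lev_p, "punif")$p.value, 0.01)

  expect_error(assumption_checks(rep(1, 20)),
               class = "eqg_degenerate_input_error")
  expect_error(assumption_checks(c(1, 2)), class = "eqg_sample_size_error")
})

test_that("sensor agreement reports r, R^2 and Bland-Altman limits", {
  x <- seq(5, 15, length.out = 20)
  same <- sensor_agreement(x, x)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$bland_altman_mean_g, 0)

  off <- sensor_agreement(x, x + 0.4)
  expect_equal(off$pearson_r, 1)
  expect_equal(off$r_squared, off$pearson_r^2, tolerance = 1e-12)
  expect_equal(off$bland_altman_mean_g, 0.4, tolerance = 1e-12)

  set.seed(47)
  x2 <- runif(500, 5, 15)
  noisy <- sensor_agreement(x2, x2 + rnorm(500, 0, 0.2))
  half_width <- diff(noisy$bland_altman_limits_g) / 2
  expect_lt(abs(half_width - 1.96 * 0.2) / (1.96 * 0.2), 0.1)
  expect_equal(mean(noisy$bland_altman_limits_g), noisy$bland_altman_mean_g,
               tolerance = 1e-12)

  expect_error(sensor_agreement(1:20, 1:19), class = "eqg_pairing_error")
  expect_error(sensor_agreement(1:5, 1:5), class = "eqg_data_error")
  expect_identical(glance(noisy), tidy(noisy))
})

test_that("hoof-on events from two streams pair by nearest time within tolerance", {
  a <- tibble::tibble(limb = "LF", hoof_on_s = c(1, 2, 3, 4), pill_g = 5:8)
  b <- tibble::tibble(limb = "LF", hoof_on_s = c(1.01, 2.02, 3.2, 4.01),
                      pill_g = c(5.1, 6.1, 99, 8.1))
  m <- pair_hoof_on_events(a, b, tolerance_ms = 50)
  expect_identical(nrow(m), 3L)
  expect_false(99 %in% m$pill_b)
  expect_error(pair_hoof_on_events(a, b, tolerance_ms = 0),
               class = "eqg_parameter_error")
})
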