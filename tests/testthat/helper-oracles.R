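# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and cor()/aov()) so they can serve as
# brute-force cross-checks.

# Long-format subject x condition table from a matrix.
long_table <- function(m, conds = letters[seq_len(ncol(m))]) {
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(nrow(m))), ncol(m)),
    cond = rep(conds, each = nrow(m)),
    y = as.vector(m))
}

# Uniformly random rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Spearman's rho from first principles: Pearson product-moment formula
# applied to ranks, written out as sums.
bruteforce_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# One-way within-subject ANOVA by explicit sums of squares on a
# subjects x conditions matrix: F, partial eta^2.
bruteforce_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- sum((m - outer(subj_means, rep(1, k)) -
                   outer(rep(1, n), cond_means) + grand)^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  list(F = (ss_cond / df1) / (ss_err / df2),
       partial_eta2 = ss_cond / (ss_cond + ss_err))
}

# Cohen's d by its definition: mean difference over pooled SD.
bruteforce_cohen_d <- function(a, b) {
  pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / pooled
}

# Minimal valid recording tibble: constant acceleration, zero gyro.
static_recording <- function(acc = c(0, 0, 1), duration_s = 2, rate_hz = 120,
                             site = "LF", euler = NULL) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  df <- tibble::tibble(
    time_s = t,
    acc_x = acc[1], acc_y = acc[2], acc_z = acc[3],
    gyr_x = 0, gyr_y = 0, gyr_z = 0)
  if (!is.null(euler)) {
    df$roll_deg <- euler[1]; df$pitch_deg <- euler[2]; df$yaw_deg <- euler[3]
  }
  imu_recording(df, site = site, rate_hz = rate_hz)
}

# A train of positive half-sine lobes (synthetic swing signal) with given
# lobe-centre times; returns the signal and the centre sample indices.
lobe_train <- function(centers, lobe_s = 0.4, amp = 300, duration_s = 40,
                       rate_hz = 120) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  y <- numeric(length(t))
  for (ctr in centers) {
    s0 <- ctr - lobe_s / 2
    idx <- which(t >= s0 & t <= s0 + lobe_s)
    y[idx] <- pmax(y[idx], amp * sin(pi * (t[idx] - s0) / lobe_s))
  }
  list(t = t, y = y, centers_idx = round(centers * rate_hz) + 1L)
}

# Gaussian pulse train on a 1 g baseline (synthetic impact magnitude).
pulse_train <- function(t, centers, peaks, sigma = 0.015) {
  y <- rep(1, length(t))
  for (i in seq_along(centers)) {
    y <- y + (peaks[i] - 1) * exp(-(t - centers[i])^2 / (2 * sigma^2))
  }
  y
}
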