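# Per-stride parameters and the longitudinal / lateral limb-load asymmetry
# indices, aggregated per trial.

#' Add stride parameters to a cycle table
#'
#' For each gait cycle: stride duration (`stride_s = cycle_end - cycle_start`),
#' stride frequency (its inverse), stance duration (`hoof_off - hoof_on`),
#' swing duration (stride minus stance) and duty factor (stance over stride).
#' Stance plus swing reconstructs the stride duration exactly.
#'
#' @param cycles Tibble with `cycle_start_s`, `hoof_on_s`, `hoof_off_s`,
#'   `cycle_end_s` (and any identifier columns, e.g. `limb`).
#' @return The input with `stride_s`, `stride_freq_hz`, `stance_ms`,
#'   `swing_ms`, `duty_factor` columns added.
#' @export
stride_parameters <- function(cycles) {
  cycles <- as_tibble(cycles)
  ok <- with(cycles, cycle_start_s <= hoof_on_s & hoof_on_s < hoof_off_s &
               hoof_off_s <= cycle_end_s)
  if (!all(ok)) {
    abort("events must satisfy cycle_start <= hoof_on < hoof_off <= cycle_end",
          class = "eqg_data_error")
  }
  cycles %>%
    mutate(
      stride_s = .data$cycle_end_s - .data$cycle_start_s,
      stride_freq_hz = 1 / .data$stride_s,
      stance_ms = 1000 * (.data$hoof_off_s - .data$hoof_on_s),
      swing_ms = 1000 * .data$stride_s - .data$stance_ms,
      duty_factor = .data$stance_ms / (1000 * .data$stride_s))
}

#' Longitudinal asymmetry index (LongAI)
#'
#' Normalised fore-vs-hind load difference,
#' `(F - H) / ((F + H) / 2) * 100` percent, where `F` and `H` are the mean
#' peak impact limb loads of the fore and hind pairs. Positive values mean
#' forelimb dominance; the index is bounded in (-200, 200).
#'
#' @param f_g,h_g Mean fore / hind PILL in g (positive).
#' @return LongAI in percent.
#' @export
long_asymmetry_index <- function(f_g, h_g) {
  if (any(f_g <= 0) || any(h_g <= 0)) {
    abort("limb loads must be positive", class = "eqg_domain_error")
  }
  (f_g - h_g) / ((f_g + h_g) / 2) * 100
}

#' Lateral asymmetry index (LatAI)
#'
#' Normalised left-vs-right load difference,
#' `(L - R) / ((L + R) / 2) * 100` percent, computed separately within the
#' fore pair and within the hind pair. Positive values mean left dominance.
#'
#' @param l_g,r_g Mean left / right PILL in g (positive).
#' @return LatAI in percent.
#' @export
lat_asymmetry_index <- function(l_g, r_g) {
  if (any(l_g <= 0) || any(r_g <= 0)) {
    abort("limb loads must be positive", class = "eqg_domain_error")
  }
  (l_g - r_g) / ((l_g + r_g) / 2) * 100
}

#' Summarise a trial's gait cycles
#'
#' Aggregation is limb means first, indices from means second: per-limb means
#' of the stride parameters and PILL are formed over strides, then the fore
#' (`F`), hind (`H`), left and right loads are unweighted means of the two
#' limb means in each pair, and the asymmetry indices are computed from those.
#' Trials with fewer than `min_strides` strides on any limb are rejected.
#'
#' @param cycles Cycle table with a `limb` column and stride parameters (from
#'   [stride_parameters()]).
#' @param meta A [trial_meta()].
#' @param min_strides Minimum strides per limb (default 3).
#' @return A `trial_summary` list with elements `trial` (one-row tibble of
#'   means plus asymmetry indices), `limb_loads` (per-limb mean PILL and
#'   stride counts) and `asymmetry` (one-row tibble of LongAI and the two
#'   LatAIs, in percent).
#' @export
summarize_trial <- function(cycles, meta, min_strides = 3) {
  stopifnot(inherits(meta, "trial_meta"))
  cycles <- as_tibble(cycles)
  counts <- table(factor(cycles$limb, levels = limb_sites))
  short <- names(counts)[counts < min_strides]
  if (length(short) > 0) {
    abort(paste0("fewer than ", min_strides, " strides on limb(s): ",
                 paste(short, collapse = ", ")),
          class = "eqg_insufficient_data_error")
  }
  limb_means <- cycles %>%
    group_by(.data$limb) %>%
    summarise(n_strides = dplyr::n(),
              pill_g = mean(.data$pill_g),
              stride_s = mean(.data$stride_s),
              stride_freq_hz = mean(.data$stride_freq_hz),
              stance_ms = mean(.data$stance_ms),
              swing_ms = mean(.data$swing_ms),
              duty_factor = mean(.data$duty_factor),
              .groups = "drop")
  g <- function(l) limb_means$pill_g[limb_means$limb == l]
  f_mean <- (g("LF") + g("RF")) / 2
  h_mean <- (g("LH") + g("RH")) / 2
  asym <- tibble(
    long_ai_pct = long_asymmetry_index(f_mean, h_mean),
    lat_ai_fore_pct = lat_asymmetry_index(g("LF"), g("RF")),
    lat_ai_hind_pct = lat_asymmetry_index(g("LH"), g("RH")))
  trial <- tibble(
    horse_id = meta$horse_id, gait = meta$gait, rein = meta$rein,
    n_strides_lf = counts[["LF"]], n_strides_rf = counts[["RF"]],
    n_strides_lh = counts[["LH"]], n_strides_rh = counts[["RH"]],
    stride_freq_hz = mean(limb_means$stride_freq_hz),
    stride_s = mean(limb_means$stride_s),
    stance_ms = mean(limb_means$stance_ms),
    swing_ms = mean(limb_means$swing_ms),
    duty_factor = mean(limb_means$duty_factor),
    pill_g = mean(limb_means$pill_g)) %>%
    dplyr::bind_cols(asym)
  structure(list(trial = trial, limb_loads = limb_means, asymmetry = asym),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary>\n")
  print(x$trial)
  invisible(x)
}

#' @rdname tidy
#' @param x A fitted/summary object from this package.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.trial_summary <- function(x, ...) x$trial

#' Spearman correlation between impact load and stance duration
#'
#' Rank correlation (with two-sided p-value) between per-stride PILL and
#' stance duration across a pooled stride table.
#'
#' @param strides Tibble with `pill_g` and `stance_ms` columns (>= 10 rows).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
correlate_pill_stance <- function(strides) {
  strides <- as_tibble(strides)
  if (nrow(strides) < 10) {
    abort("need at least 10 strides", class = "eqg_data_error")
  }
  x <- strides$pill_g; y <- strides$stance_ms
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "eqg_undefined_correlation_error")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "two.sided",
             exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
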