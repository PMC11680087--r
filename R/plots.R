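# ggplot2 views of recordings, detected events and result objects.

#' Plot a trial's acceleration magnitude with detected events
#'
#' One facet per limb: unfiltered acceleration magnitude over time, with
#' hoof-on (circles) and hoof-off (triangles) marks when a cycle table is
#' supplied.
#'
#' @param trial A [trial_recording()].
#' @param cycles Optional cycle table from [analyze_trial()].
#' @param window Optional length-2 time window (s) to restrict the view.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, cycles = NULL, window = NULL) {
  traces <- purrr::map_dfr(limb_sites, function(l) {
    rec <- trial$recordings[[l]]
    tibble(limb = l, time_s = rec$time_s,
           acc_mag_g = acceleration_magnitude(rec))
  })
  if (!is.null(window)) {
    traces <- filter(traces, .data$time_s >= window[1],
                     .data$time_s <= window[2])
  }
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time_s, y = .data$acc_mag_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~limb, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "|a| (g)")
  if (!is.null(cycles)) {
    ev <- as_tibble(cycles)
    if (!is.null(window)) {
      ev <- filter(ev, .data$hoof_on_s >= window[1],
                   .data$hoof_on_s <= window[2])
    }
    p <- p +
      ggplot2::geom_point(data = ev, colour = "red", shape = 1, size = 2,
                          ggplot2::aes(x = .data$hoof_on_s, y = .data$pill_g)) +
      ggplot2::geom_vline(data = ev, linetype = 3, colour = "grey50",
                          ggplot2::aes(xintercept = .data$cycle_start_s))
  }
  p
}

#' Asymmetry overview of a trial-summary table
#'
#' Longitudinal and lateral asymmetry indices per trial, grouped by gait.
#'
#' @param summaries Trial-summary tibble (rows from [analyze_cohort()]).
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(summaries) {
  long <- tidyr::pivot_longer(
    as_tibble(summaries),
    c("long_ai_pct", "lat_ai_fore_pct", "lat_ai_hind_pct"),
    names_to = "index", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gait, y = .data$pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "asymmetry index (%)")
}

#' @rdname sensor_agreement
#' @param object An `eqg_agreement` object (for `autoplot`).
#' @param first,second The matched series used to fit `object`; required for
#'   the scatter/Bland-Altman view.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.eqg_agreement <- function(object, first = NULL, second = NULL, ...) {
  if (is.null(first) || is.null(second)) {
    abort("supply the matched series: autoplot(x, first =, second =)",
          class = "eqg_parameter_error")
  }
  d <- tibble(mean_g = (first + second) / 2, diff_g = second - first)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_g, y = .data$diff_g)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bland_altman_mean_g,
                        colour = "blue") +
    ggplot2::geom_hline(yintercept = object$bland_altman_limits_g,
                        linetype = 2, colour = "blue") +
    ggplot2::labs(x = "pair mean (g)",
                  y = "difference, second - first (g)")
}
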