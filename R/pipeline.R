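# End-to-end orchestration: configuration, per-trial analysis, cohort runs,
# simulation to disk and detection-vs-truth evaluation.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its documented
#' default: the 20 Hz second-order zero-phase low-pass, whether the
#' acceleration magnitude is filtered before peak picking (`filter_acc`), the
#' impact-candidate floor (2 g) and robust threshold multiplier (4 MAD), the
#' 50 ms refractory separation, the cycle-segmentation fractions, the edge
#' exclusion, the PILL readout window, the unit hint for CSV input and the
#' minimum strides per limb for a trial summary.
#'
#' @param filter A [filter_spec()].
#' @param filter_acc Filter the acceleration magnitude before peak picking?
#' @param unit_hint Passed to [read_recording()].
#' @param min_strides Minimum strides per limb (default 3).
#' @param min_peak_g,mad_k,refractory_ms,pill_window_ms See
#'   [detect_hoof_events()].
#' @param min_sep_frac,prom_frac,edge_s,max_cycle_frac See [segment_cycles()].
#' @param period_band Pitch-spectrum search band in Hz.
#' @return An `eqg_config` list.
#' @export
eqg_config <- function(filter = filter_spec(), filter_acc = TRUE,
                       unit_hint = "auto", min_strides = 3,
                       min_peak_g = 2, mad_k = 4, refractory_ms = 50,
                       pill_window_ms = 25, min_sep_frac = 0.7,
                       prom_frac = 0.3, edge_s = 0.5, max_cycle_frac = 1.8,
                       period_band = c(0.4, 2.5)) {
  structure(list(filter = filter, filter_acc = filter_acc,
                 unit_hint = unit_hint, min_strides = min_strides,
                 min_peak_g = min_peak_g, mad_k = mad_k,
                 refractory_ms = refractory_ms,
                 pill_window_ms = pill_window_ms,
                 min_sep_frac = min_sep_frac, prom_frac = prom_frac,
                 edge_s = edge_s, max_cycle_frac = max_cycle_frac,
                 period_band = period_band),
            class = "eqg_config")
}

#' @export
print.eqg_config <- function(x, ...) {
  cat(yaml::as.yaml(config_as_list(x)))
  invisible(x)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out
}

#' Load a configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#' @param path YAML file path.
#' @return An [eqg_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- eqg_config()
  bad <- setdiff(names(y), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "eqg_format_error")
  }
  args <- config_as_list(defaults)
  args <- modifyList(args, y)
  args$filter <- do.call(filter_spec, as.list(args$filter))
  do.call(eqg_config, args)
}

#' Analyse one trial
#'
#' Runs the full per-trial chain: per limb, the cycle period is estimated
#' from the pitch angle, cycles are segmented from the sign-normalised
#' sagittal angular velocity, hoof-on/hoof-off events and PILL are detected
#' from the acceleration magnitude, stride parameters are derived and the
#' trial is summarised (limb means, then asymmetry indices).
#'
#' @param trial A [trial_recording()].
#' @param config An [eqg_config()].
#' @return List with `cycles` (per-stride tibble including identifiers),
#'   `summary` (a [summarize_trial()] result) and `log` (per-limb period,
#'   stride counts, dropped cycles and thresholds used).
#' @export
analyze_trial <- function(trial, config = eqg_config()) {
  stopifnot(inherits(trial, "trial_recording"), inherits(config, "eqg_config"))
  meta <- trial$meta
  all_cycles <- list()
  pill_inputs <- list()
  log <- list(thresholds = config_as_list(config), limbs = list())
  for (limb in limb_sites) {
    rec <- trial$recordings[[limb]]
    rate <- rec_rate(rec)
    fspec <- filter_spec(config$filter$order, config$filter$cutoff_hz, rate)
    pitch <- pitch_angle(rec)
    period <- estimate_cycle_period(pitch, rate_hz = rate,
                                    band = config$period_band)
    gyr_sag <- sagittal_angular_velocity(rec)
    boundaries <- segment_cycles(gyr_sag, period, spec = fspec,
                                 min_sep_frac = config$min_sep_frac,
                                 prom_frac = config$prom_frac,
                                 edge_s = config$edge_s,
                                 max_cycle_frac = config$max_cycle_frac)
    acc_raw <- acceleration_magnitude(rec)
    acc_det <- if (config$filter_acc) lowpass(acc_raw, fspec) else acc_raw
    det <- detect_hoof_events(acc_det, boundaries, rate_hz = rate,
                              acc_raw = acc_raw, t = rec$time_s,
                              min_peak_g = config$min_peak_g,
                              mad_k = config$mad_k,
                              refractory_ms = config$refractory_ms,
                              pill_window_ms = config$pill_window_ms)
    cycles <- det$cycles %>% mutate(limb = limb, .before = 1)
    all_cycles[[limb]] <- cycles
    pill_inputs[[limb]] <- det$pill_input
    log$limbs[[limb]] <- list(period_s = period,
                              n_cycles = nrow(cycles),
                              dropped = det$dropped)
  }
  # refine the PILL readout with the impact-pulse template pooled across the
  # four limbs: its scale error is then common to all limbs and cancels in
  # the asymmetry indices
  window_sets <- lapply(pill_inputs, function(pi) {
    pill_windows(pi$acc_raw, pi$i_on, pi$baseline, pi$win)
  })
  if (all(vapply(window_sets, function(pw) sum(pw$ok), integer(1)) >= 5)) {
    shape <- pill_shape(window_sets)
    for (limb in limb_sites) {
      pi <- pill_inputs[[limb]]
      all_cycles[[limb]]$pill_g <- pill_amplitude(
        pi$acc_raw, pi$i_on, pi$baseline, pi$win, shape = shape)
    }
  }
  cycles <- bind_rows(all_cycles) %>%
    stride_parameters() %>%
    mutate(horse_id = meta$horse_id, gait = meta$gait, rein = meta$rein,
           .before = 1)
  summary <- summarize_trial(cycles, meta, min_strides = config$min_strides)
  list(cycles = cycles, summary = summary, log = log)
}

#' Analyse a cohort of trials
#'
#' Takes a cohort manifest -- a YAML file with a `trials:` list of per-trial
#' manifest paths (relative to it), or an in-memory list of
#' [trial_recording()]s -- and writes `stride_table.csv`,
#' `trial_summary.csv`, `asymmetry.csv` and `run_log.yaml` to `out_dir`.
#' Failures are isolated per trial: one bad trial is logged and skipped, and
#' an error is raised only if every trial fails.
#'
#' @param trials Cohort manifest path or list of [trial_recording()]s.
#' @param out_dir Output directory.
#' @param config An [eqg_config()].
#' @return Invisibly, a list with `summaries`, `cycles`, `failures`.
#' @export
analyze_cohort <- function(trials, out_dir, config = eqg_config()) {
  if (is.character(trials)) {
    man <- yaml::read_yaml(trials)
    if (is.null(man$trials) || length(man$trials) == 0) {
      abort("cohort manifest lists no trials", class = "eqg_format_error")
    }
    base <- dirname(trials)
    paths <- vapply(man$trials, function(p) {
      if (grepl("^/", p)) p else file.path(base, p)
    }, character(1))
    loader <- function(i) read_trial_manifest(paths[i],
                                              unit_hint = config$unit_hint)
    n <- length(paths)
    labels <- paths
  } else {
    loader <- function(i) trials[[i]]
    n <- length(trials)
    labels <- paste0("trial_", seq_len(n))
    if (n == 0) abort("no trials to analyse", class = "eqg_format_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cycles <- list(); summaries <- list(); logs <- list(); failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(analyze_trial(loader(i), config), error = identity)
    if (inherits(res, "error")) {
      failures[[labels[i]]] <- conditionMessage(res)
      next
    }
    cycles[[i]] <- res$cycles
    summaries[[i]] <- res$summary$trial
    logs[[labels[i]]] <- res$log$limbs
  }
  if (length(summaries) == 0) {
    abort("all trials failed to analyse", class = "eqg_detection_failure_error")
  }
  cycles <- bind_rows(cycles)
  summaries <- bind_rows(summaries)
  write_stride_table(cycles, file.path(out_dir, "stride_table.csv"))
  readr::write_csv(summaries, file.path(out_dir, "trial_summary.csv"),
                   progress = FALSE)
  readr::write_csv(
    summaries[, c("horse_id", "gait", "rein", "long_ai_pct",
                  "lat_ai_fore_pct", "lat_ai_hind_pct")],
    file.path(out_dir, "asymmetry.csv"), progress = FALSE)
  yaml::write_yaml(list(trials = logs, failures = failures),
                   file.path(out_dir, "run_log.yaml"))
  invisible(list(summaries = summaries, cycles = cycles, failures = failures))
}

#' Simulate a cohort to disk
#'
#' Materialises every trial of a [generate_cohort()] manifest under
#' `out_dir/<horse>/<gait>_<trial>/` (per-sensor CSVs plus trial manifest and
#' per-stride ground truth), and writes `cohort.yaml` (trial manifest list),
#' `cohort_manifest.csv` (the full generation manifest with true asymmetry
#' indices) and `ground_truth.csv` (all per-stride events).
#'
#' @param manifest A [generate_cohort()] manifest.
#' @param out_dir Output directory.
#' @return Invisibly, the path to `cohort.yaml`.
#' @export
simulate_cohort <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial_manifests <- character(0)
  truths <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sim <- cohort_trial(row)
    rel <- file.path(row$horse_id, sprintf("%s_%d", row$gait, row$trial))
    dir <- file.path(out_dir, rel)
    write_trial(sim$trial, dir)
    write_ground_truth(sim$truth, file.path(dir, "truth.csv"))
    trial_manifests <- c(trial_manifests, file.path(rel, "manifest.yaml"))
    truths[[i]] <- sim$truth$events %>%
      mutate(horse_id = row$horse_id, gait = row$gait, trial = row$trial,
             .before = 1)
  }
  yaml::write_yaml(list(trials = as.list(trial_manifests)),
                   file.path(out_dir, "cohort.yaml"))
  readr::write_csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
                   progress = FALSE)
  readr::write_csv(bind_rows(truths), file.path(out_dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(file.path(out_dir, "cohort.yaml"))
}

#' Compare detected events against ground truth
#'
#' Greedy nearest-time matching of detected to true hoof-on events within
#' `tolerance_ms`, per limb. Reports recall (matched / true), precision
#' (matched / detected), RMS timing errors of hoof-on and hoof-off over the
#' matched strides, and the mean absolute relative PILL errors, per stride
#' and of the per-limb mean loads.
#'
#' @param detected Cycle table with `limb, hoof_on_s, hoof_off_s, pill_g`.
#' @param truth Ground-truth events with `limb, t_on_s, t_off_s, peak_g`.
#' @param tolerance_ms Matching tolerance (> 0), default 25 ms.
#' @return One-row tibble: `n_true, n_detected, n_matched, recall, precision,
#'   rmse_on_ms, rmse_off_ms, pill_mare_pct, pill_mean_err_pct`.
#' @export
evaluate_events <- function(detected, truth, tolerance_ms = 25) {
  if (tolerance_ms <= 0) {
    abort("tolerance_ms must be positive", class = "eqg_parameter_error")
  }
  detected <- as_tibble(detected); truth <- as_tibble(truth)
  err_on <- c(); err_off <- c(); rel_pill <- c()
  n_matched <- 0L
  mean_errs <- c()
  for (l in unique(truth$limb)) {
    dt <- detected[detected$limb == l, ]
    tr <- truth[truth$limb == l, ]
    m <- match_events(tr$t_on_s, dt$hoof_on_s, tolerance_ms / 1000)
    n_matched <- n_matched + nrow(m)
    if (nrow(m) == 0) next
    err_on <- c(err_on, dt$hoof_on_s[m$j] - tr$t_on_s[m$i])
    err_off <- c(err_off, dt$hoof_off_s[m$j] - tr$t_off_s[m$i])
    rel_pill <- c(rel_pill,
                  (dt$pill_g[m$j] - tr$peak_g[m$i]) / tr$peak_g[m$i])
    mean_errs <- c(mean_errs,
                   abs(mean(dt$pill_g[m$j]) - mean(tr$peak_g[m$i])) /
                     mean(tr$peak_g[m$i]))
  }
  rmse <- function(e) if (length(e) == 0) NA_real_ else sqrt(mean(e^2))
  tibble(
    n_true = nrow(truth), n_detected = nrow(detected), n_matched = n_matched,
    recall = n_matched / nrow(truth),
    precision = n_matched / nrow(detected),
    rmse_on_ms = 1000 * rmse(err_on),
    rmse_off_ms = 1000 * rmse(err_off),
    pill_mare_pct = if (length(rel_pill)) 100 * mean(abs(rel_pill)) else NA_real_,
    pill_mean_err_pct = if (length(mean_errs)) 100 * mean(mean_errs) else NA_real_)
}
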