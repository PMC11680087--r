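# Cohort-level repeated-measures statistics and the two-sensor agreement
# analysis, operating on trial-summary tables.

#' Repeated-measures ANOVA with partial eta squared
#'
#' One- or two-factor within-subject ANOVA on a long table. Trial-level
#' values are first averaged to one value per subject and condition cell; the
#' table must then be complete and balanced (no imputation). Univariate
#' within-subject F tests are computed (via a multivariate linear model, as
#' `car::Anova` does), with Mauchly's sphericity test and the
#' Greenhouse-Geisser correction; the reported p-value uses the corrected
#' test whenever Mauchly's p < 0.05, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of one or two within-subject factor columns.
#' @param sphericity_alpha Mauchly threshold for applying the correction.
#' @return An `eqg_rm_anova` object; `tidy()` gives one row per effect with
#'   `effect, df_num, df_den, statistic, p_uncorrected, mauchly_p,
#'   gg_epsilon, p_gg, p_value, partial_eta2`.
#' @export
rm_anova <- function(data, dv, subject, within, sphericity_alpha = 0.05) {
  data <- as_tibble(data)
  cols <- c(dv, subject, within)
  if (!all(cols %in% names(data))) {
    abort(paste0("missing column(s): ",
                 paste(setdiff(cols, names(data)), collapse = ", ")),
          class = "eqg_format_error")
  }
  if (length(within) < 1 || length(within) > 2) {
    abort("within must name one or two factors", class = "eqg_parameter_error")
  }
  agg <- data %>%
    group_by(across(all_of(c(subject, within)))) %>%
    summarise(.value = mean(.data[[dv]]), .groups = "drop")
  lv <- lapply(within, function(w) sort(unique(as.character(agg[[w]]))))
  names(lv) <- within
  subjects <- sort(unique(as.character(agg[[subject]])))
  n_cells <- prod(vapply(lv, length, integer(1)))
  if (nrow(agg) != length(subjects) * n_cells) {
    abort("design is not complete and balanced; every subject needs every condition",
          class = "eqg_balance_error")
  }
  idata <- do.call(expand.grid,
                   c(lv, list(stringsAsFactors = TRUE,
                              KEEP.OUT.ATTRS = FALSE)))
  y <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(idata))
  key_agg <- do.call(paste, c(lapply(within, function(w) as.character(agg[[w]])),
                              sep = "\r"))
  key_cell <- do.call(paste, c(lapply(within, function(w) as.character(idata[[w]])),
                               sep = "\r"))
  for (j in seq_len(nrow(idata))) {
    cell <- agg[key_agg == key_cell[j], ]
    if (nrow(cell) != length(subjects)) {
      abort("design is not complete and balanced; every subject needs every condition",
            class = "eqg_balance_error")
    }
    y[, j] <- cell$.value[match(subjects, as.character(cell[[subject]]))]
  }
  mlm <- lm(y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # Huynh-Feldt epsilon > 1 is routinely clamped; the warning is noise here
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  univ <- s$univariate.tests
  effects <- setdiff(rownames(univ), "(Intercept)")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  res <- lapply(effects, function(e) {
    ss <- univ[e, "Sum Sq"]; ess <- univ[e, "Error SS"]
    f <- univ[e, "F value"]
    mau <- if (!is.null(sph) && e %in% rownames(sph)) sph[e, "p-value"] else NA_real_
    eps <- if (!is.null(adj) && e %in% rownames(adj)) adj[e, "GG eps"] else NA_real_
    pgg <- if (!is.null(adj) && e %in% rownames(adj)) adj[e, "Pr(>F[GG])"] else NA_real_
    p_un <- univ[e, "Pr(>F)"]
    p_rep <- if (!is.na(mau) && mau < sphericity_alpha && !is.na(pgg)) pgg else p_un
    tibble(effect = e,
           df_num = unname(univ[e, "num Df"]),
           df_den = unname(univ[e, "den Df"]),
           statistic = unname(f),
           p_uncorrected = unname(p_un),
           mauchly_p = unname(mau),
           gg_epsilon = unname(eps),
           p_gg = unname(pgg),
           p_value = unname(p_rep),
           partial_eta2 = unname(if (ss + ess == 0) 0 else ss / (ss + ess)))
  })
  structure(list(table = bind_rows(res), n_subjects = length(subjects),
                 within = within, dv = dv,
                 sphericity_alpha = sphericity_alpha),
            class = "eqg_rm_anova")
}

#' @export
print.eqg_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects; within: %s)\n",
              x$n_subjects, paste(x$within, collapse = " x ")))
  cat(sprintf("Greenhouse-Geisser applied when Mauchly p < %.2f\n",
              x$sphericity_alpha))
  print(x$table)
  invisible(x)
}

#' @rdname tidy
#' @exportS3Method generics::tidy
#' @export
tidy.eqg_rm_anova <- function(x, ...) x$table

#' @rdname tidy
#' @exportS3Method generics::glance
#' @export
glance.eqg_rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_effects = nrow(x$table),
         dv = x$dv, design = paste(x$within, collapse = " x "))
}

#' Tukey post hoc comparisons with Cohen's d
#'
#' All pairwise comparisons of one within-subject factor, Tukey-adjusted on a
#' subject-blocked ANOVA of the per-cell means. Cohen's d is the mean
#' difference over the pooled SD of the two conditions' values, labelled
#' negligible / small / medium / large at |d| = 0.2 / 0.5 / 0.8.
#'
#' @inheritParams rm_anova
#' @param within Single within-subject factor name.
#' @return Tibble with `comparison, estimate, p_adj, cohen_d, magnitude`.
#' @export
posthoc_tukey <- function(data, dv, subject, within) {
  stopifnot(length(within) == 1)
  data <- as_tibble(data)
  agg <- data %>%
    group_by(across(all_of(c(subject, within)))) %>%
    summarise(.value = mean(.data[[dv]]), .groups = "drop")
  counts <- table(agg[[subject]], agg[[within]])
  if (any(counts != 1)) {
    abort("design is not complete and balanced; every subject needs every condition",
          class = "eqg_balance_error")
  }
  cond <- factor(agg[[within]])
  subj <- factor(agg[[subject]])
  fit <- aov(agg$.value ~ cond + subj)
  tk <- suppressWarnings(TukeyHSD(fit, "cond"))$cond
  out <- lapply(rownames(tk), function(cmp) {
    pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    a <- agg$.value[cond == pair[1]]
    b <- agg$.value[cond == pair[2]]
    diff <- mean(a) - mean(b)
    pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                     (length(a) + length(b) - 2))
    d <- if (pooled == 0) {
      if (diff == 0) 0 else Inf * sign(diff)
    } else diff / pooled
    p <- tk[cmp, "p adj"]
    if (!is.finite(p) && diff == 0) p <- 1
    tibble(comparison = cmp, estimate = diff, p_adj = p,
           cohen_d = d, magnitude = effect_size_label(d))
  })
  bind_rows(out)
}

#' Effect-size magnitude labels
#'
#' Cohen's bands: |d| < 0.2 negligible, 0.2-0.5 small, 0.5-0.8 medium,
#' >= 0.8 large.
#' @param d Cohen's d value(s).
#' @return Character vector of labels.
#' @export
effect_size_label <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE) %>% as.character()
}

#' Distributional assumption checks
#'
#' Shapiro-Wilk normality per group (or overall) and, when groups are given,
#' Levene's homoscedasticity test (mean-centred, the original form). These
#' checks are advisory: the pipeline never switches tests automatically.
#'
#' @param values Numeric vector.
#' @param group Optional grouping vector of the same length.
#' @return Tibble with `test, group, statistic, p_value`.
#' @export
assumption_checks <- function(values, group = NULL) {
  if (!is.null(group) && length(group) != length(values)) {
    abort("group must match values in length", class = "eqg_data_error")
  }
  check_n <- function(v) {
    if (length(v) < 3) abort("need at least 3 observations per group",
                             class = "eqg_sample_size_error")
    if (sd(v) == 0) abort("degenerate (constant) sample",
                          class = "eqg_degenerate_input_error")
  }
  if (is.null(group)) {
    check_n(values)
    sw <- shapiro.test(values)
    return(tibble(test = "shapiro_wilk", group = NA_character_,
                  statistic = unname(sw$statistic), p_value = sw$p.value))
  }
  group <- as.character(group)
  rows <- lapply(split(values, group), function(v) v)
  out <- list()
  for (gname in names(rows)) {
    v <- rows[[gname]]
    check_n(v)
    sw <- shapiro.test(v)
    out[[length(out) + 1L]] <- tibble(
      test = "shapiro_wilk", group = gname,
      statistic = unname(sw$statistic), p_value = sw$p.value)
  }
  lev <- car::leveneTest(values ~ factor(group), center = mean)
  out[[length(out) + 1L]] <- tibble(
    test = "levene", group = NA_character_,
    statistic = lev[1, "F value"], p_value = lev[1, "Pr(>F)"])
  bind_rows(out)
}

#' Agreement between two co-located sensor types
#'
#' Pearson correlation with R squared, and Bland-Altman mean difference
#' (second minus first) with 1.96 SD limits of agreement, for matched peak
#' impact magnitudes from two sensors measuring the same strides.
#'
#' @param first,second Matched peak magnitudes (g); equal length, >= 10 pairs.
#' @return An `eqg_agreement` object (`tidy()`/`glance()` supported).
#' @export
sensor_agreement <- function(first, second) {
  if (length(first) != length(second)) {
    abort("paired series must have equal length", class = "eqg_pairing_error")
  }
  if (length(first) < 10) {
    abort("need at least 10 matched pairs", class = "eqg_data_error")
  }
  d <- second - first
  r <- cor(first, second)
  structure(list(
    pearson_r = r, r_squared = r^2,
    bland_altman_mean_g = mean(d),
    bland_altman_sd_g = sd(d),
    bland_altman_limits_g = mean(d) + c(-1, 1) * 1.96 * sd(d),
    n_pairs = length(first)), class = "eqg_agreement")
}

#' @export
print.eqg_agreement <- function(x, ...) {
  cat(sprintf(
    "Sensor agreement on %d pairs: r = %.3f (R^2 = %.3f)\nBland-Altman mean difference %.3f g, limits [%.3f, %.3f] g\n",
    x$n_pairs, x$pearson_r, x$r_squared, x$bland_altman_mean_g,
    x$bland_altman_limits_g[1], x$bland_altman_limits_g[2]))
  invisible(x)
}

#' @rdname tidy
#' @exportS3Method generics::tidy
#' @export
tidy.eqg_agreement <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, r_squared = x$r_squared,
         bland_altman_mean_g = x$bland_altman_mean_g,
         loa_lower_g = x$bland_altman_limits_g[1],
         loa_upper_g = x$bland_altman_limits_g[2],
         n_pairs = x$n_pairs)
}

#' @rdname tidy
#' @exportS3Method generics::glance
#' @export
glance.eqg_agreement <- function(x, ...) tidy(x)

#' Pair hoof-on events from two sensor streams
#'
#' Matches each stride's hoof-on in the first stream to the nearest-in-time
#' hoof-on in the second within `tolerance_ms` (each event used once), per
#' limb, returning the matched PILL pairs for [sensor_agreement()].
#'
#' @param a,b Cycle tables with `limb`, `hoof_on_s`, `pill_g`.
#' @param tolerance_ms Maximum time offset for a match (default 50 ms).
#' @return Tibble with `limb, pill_a, pill_b, dt_ms`.
#' @export
pair_hoof_on_events <- function(a, b, tolerance_ms = 50) {
  if (tolerance_ms <= 0) abort("tolerance must be positive",
                               class = "eqg_parameter_error")
  out <- list()
  for (l in intersect(unique(a$limb), unique(b$limb))) {
    m <- match_events(a$hoof_on_s[a$limb == l], b$hoof_on_s[b$limb == l],
                      tolerance_ms / 1000)
    if (nrow(m) == 0) next
    pa <- a$pill_g[a$limb == l][m$i]
    pb <- b$pill_g[b$limb == l][m$j]
    out[[l]] <- tibble(limb = l, pill_a = pa, pill_b = pb,
                       dt_ms = 1000 * m$dt)
  }
  bind_rows(out)
}

# Greedy nearest-time matching: pairs ordered by |dt|, each event used once.
match_events <- function(ta, tb, tol_s) {
  if (length(ta) == 0 || length(tb) == 0) {
    return(tibble(i = integer(), j = integer(), dt = numeric()))
  }
  cand <- expand.grid(i = seq_along(ta), j = seq_along(tb))
  cand$dt <- tb[cand$j] - ta[cand$i]
  cand <- cand[abs(cand$dt) <= tol_s, ]
  cand <- cand[order(abs(cand$dt)), ]
  used_i <- logical(length(ta)); used_j <- logical(length(tb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_i[cand$i[r]] && !used_j[cand$j[r]]) {
      keep[r] <- TRUE
      used_i[cand$i[r]] <- TRUE
      used_j[cand$j[r]] <- TRUE
    }
  }
  as_tibble(cand[keep, ])
}
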