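#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate per group; censored animals leave the risk set
#' without contributing a death event.
#'
#' @param cohort Tibble with columns `time_days`, `event` (logical) and,
#'   when `by` is used, the grouping column.
#' @param by Optional name of a grouping column (e.g. `"group"`); one curve
#'   per level.
#' @return A `km_fit` tibble: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' cohort <- tibble::tibble(time_days = c(1, 2, 3), event = TRUE)
#' km_estimate(cohort)$survival
km_estimate <- function(cohort, by = NULL) {
  check_cohort(cohort)
  groups <- if (is.null(by)) list(all = cohort)
            else split(cohort, cohort[[by]])
  if (any(vapply(groups, nrow, 0L) == 0)) {
    stop_gsc("empty group in survival cohort", "gscsoma_format_error")
  }
  out <- purrr::imap_dfr(groups, function(d, g) {
    sf <- survival::survfit(survival::Surv(d$time_days, d$event) ~ 1)
    tibble::tibble(group = g, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, n_censor = sf$n.censor,
                   survival = sf$surv)
  })
  if (is.null(by)) out$group <- NULL
  class(out) <- c("km_fit", class(out))
  out
}

check_cohort <- function(cohort) {
  if (!all(c("time_days", "event") %in% names(cohort))) {
    stop_gsc("cohort needs columns time_days and event", "gscsoma_format_error")
  }
  if (nrow(cohort) == 0) stop_gsc("empty cohort", "gscsoma_format_error")
  if (any(cohort$time_days <= 0)) {
    stop_gsc("survival times must be positive", "gscsoma_format_error")
  }
  if (!is.logical(cohort$event)) {
    stop_gsc("`event` must be logical (TRUE = death observed)",
             "gscsoma_format_error")
  }
  invisible(cohort)
}

#' @describeIn km_estimate Step-function survival curves.
#' @param object,... Method arguments.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (is.null(d$group)) d$group <- "all"
  # prepend S(0) = 1 for each curve
  d0 <- dplyr::distinct(d, .data$group)
  d0$time <- 0; d0$survival <- 1
  dd <- dplyr::bind_rows(d0, d[c("group", "time", "survival")])
  ggplot2::ggplot(dd, ggplot2::aes(.data$time, .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "fraction surviving")
}

#' Log-rank test between two survival groups
#'
#' Standard (unweighted) log-rank statistic on shared risk sets, 1 degree
#' of freedom, two-sided p. Censored records shrink the risk sets only.
#'
#' @param cohort Survival tibble (see [km_estimate()]).
#' @param group_a,group_b Levels of `by` to compare; default the only two.
#' @param by Grouping column name (default `"group"`).
#' @return One-row tibble: `chisq`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(cohort, group_a = NULL, group_b = NULL, by = "group") {
  check_cohort(cohort)
  g <- cohort[[by]]
  if (is.null(group_a)) {
    lev <- unique(g)
    if (length(lev) != 2) {
      stop_gsc("specify group_a/group_b when the cohort has != 2 groups",
               "gscsoma_format_error")
    }
    group_a <- lev[1]; group_b <- lev[2]
  }
  d <- cohort[g %in% c(group_a, group_b), ]
  grp <- factor(d[[by]], levels = c(group_a, group_b))
  if (any(table(grp) == 0)) {
    stop_gsc("both groups must be non-empty", "gscsoma_format_error")
  }
  if (sum(d$event) == 0) {
    stop_gsc("no death events: the log-rank test is undefined",
             "gscsoma_format_error")
  }
  sd <- survival::survdiff(survival::Surv(d$time_days, d$event) ~ grp)
  tibble::tibble(chisq = sd$chisq, df = 1,
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n_a = sum(grp == group_a), n_b = sum(grp == group_b))
}

#' Percent lifespan (or survival) extension
#'
#' `100 * (mean_treatment / mean_control - 1)`, reported to two decimals —
#' the arithmetic behind a lifespan table's "% extension" column.
#'
#' @param mean_treatment,mean_control Positive means (vectorized).
#' @return Percent extension, rounded to 2 decimals.
#' @export
#' @examples
#' percent_extension(19.94, 15.40)   # 29.48
percent_extension <- function(mean_treatment, mean_control) {
  if (any(mean_control <= 0) || any(mean_treatment <= 0)) {
    stop_gsc("means must be positive", "gscsoma_format_error")
  }
  round(100 * (mean_treatment / mean_control - 1), 2)
}

#' Two-way interaction ANOVA from summary cells
#'
#' Reconstructs a two-way ANOVA from per-cell summary statistics
#' (mean, SEM, n), as when only a table of group means is available. The
#' within-cell variance is recovered as `SEM^2 * n`, pooled into the error
#' mean square over `sum(n_ij - 1)` degrees of freedom; factor and
#' interaction sums of squares use unweighted cell means with the harmonic
#' mean cell size, which reproduces the raw-data ANOVA exactly when the
#' design is balanced.
#'
#' @param cells Tibble with one row per cell and columns `factor1`,
#'   `factor2`, `mean`, `sem`, `n` (`n >= 2` everywhere). An `a x b`
#'   complete layout is required (2 x 2 in the typical
#'   genotype-by-treatment lifespan design).
#' @return One-row tibble: interaction and main-effect F statistics with
#'   their p-values and degrees of freedom.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   factor1 = c("WT", "WT", "mut", "mut"),
#'   factor2 = c("ctrl", "trt", "ctrl", "trt"),
#'   mean = c(15.40, 14.66, 19.94, 15.23),
#'   sem = c(0.2, 0.2, 0.3, 0.2),
#'   n = c(133, 158, 164, 149))
#' anova2_from_summary(cells)
anova2_from_summary <- function(cells) {
  needed <- c("factor1", "factor2", "mean", "sem", "n")
  if (!all(needed %in% names(cells))) {
    stop_gsc(paste("`cells` needs columns:", paste(needed, collapse = ", ")),
             "gscsoma_format_error")
  }
  if (any(cells$n < 2)) {
    stop_gsc("every cell needs n >= 2", "gscsoma_format_error")
  }
  if (any(cells$sem < 0) || any(cells$mean <= 0)) {
    stop_gsc("cell means must be positive and SEMs non-negative",
             "gscsoma_format_error")
  }
  f1 <- unique(cells$factor1); f2 <- unique(cells$factor2)
  a <- length(f1); b <- length(f2)
  if (nrow(cells) != a * b) {
    stop_gsc("`cells` must form a complete factor1 x factor2 layout",
             "gscsoma_format_error")
  }
  m <- matrix(NA_real_, a, b, dimnames = list(f1, f2))
  nn <- m; s2 <- m
  for (i in seq_len(nrow(cells))) {
    m[cells$factor1[i], cells$factor2[i]] <- cells$mean[i]
    nn[cells$factor1[i], cells$factor2[i]] <- cells$n[i]
    s2[cells$factor1[i], cells$factor2[i]] <- cells$sem[i]^2 * cells$n[i]
  }
  sse <- sum((nn - 1) * s2)
  df_err <- sum(nn) - a * b
  mse <- sse / df_err
  n_h <- a * b / sum(1 / nn)

  grand <- mean(m)
  r_eff <- rowMeans(m) - grand
  c_eff <- colMeans(m) - grand
  inter <- m - outer(rowMeans(m), colMeans(m), "+") + grand

  ss_a <- n_h * b * sum(r_eff^2)
  ss_b <- n_h * a * sum(c_eff^2)
  ss_ab <- n_h * sum(inter^2)
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b

  f_of <- function(ss, df) (ss / df) / mse
  tibble::tibble(
    F_interaction = f_of(ss_ab, df_ab),
    p_interaction = pf(f_of(ss_ab, df_ab), df_ab, df_err, lower.tail = FALSE),
    F_factor1 = f_of(ss_a, df_a),
    p_factor1 = pf(f_of(ss_a, df_a), df_a, df_err, lower.tail = FALSE),
    F_factor2 = f_of(ss_b, df_b),
    p_factor2 = pf(f_of(ss_b, df_b), df_b, df_err, lower.tail = FALSE),
    df_interaction = df_ab, df_error = df_err
  )
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts p-values ascending, applies the Sidak correction with a shrinking
#' family size (`adj_i = 1 - (1 - p_i)^(m - i + 1)`), enforces
#' monotonicity, and restores the input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))   # 0.0199, 0.04
holm_sidak_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_gsc("p-values must lie in [0, 1]", "gscsoma_format_error")
  }
  m <- length(pvals)
  o <- order(pvals)
  adj <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  adj[order(o)]
}

#' Pearson chi-squared test on a categorical score table
#'
#' Two-sided chi-squared on the groups x categories contingency table, no
#' continuity correction, `df = (r - 1)(c - 1)`.
#'
#' @param table A tibble with a `group` column plus one integer column per
#'   category (as from [simulate_score_table()]), or a plain numeric matrix.
#' @return One-row tibble: `chisq`, `df`, `p_value`.
#' @export
chi2_score_test <- function(table) {
  m <- if (is.matrix(table)) table
       else as.matrix(tibble::column_to_rownames(tibble::as_tibble(table), "group"))
  if (nrow(m) < 2) stop_gsc("need at least two groups", "gscsoma_format_error")
  if (any(m < 0)) stop_gsc("counts must be non-negative", "gscsoma_format_error")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_gsc("zero row or column marginal: expected counts undefined",
             "gscsoma_format_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(chisq = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Normalize whole-animal fluorescence to body size
#'
#' Flow-sorter GFP intensity divided by time-of-flight (a proxy for animal
#' length), per animal.
#'
#' @param gfp Fluorescence values (>= 0).
#' @param tof Time-of-flight values (> 0).
#' @return `gfp / tof`, vectorized.
#' @export
copas_normalize <- function(gfp, tof) {
  if (any(tof <= 0)) stop_gsc("TOF values must be positive", "gscsoma_format_error")
  if (any(gfp < 0)) stop_gsc("GFP values must be non-negative", "gscsoma_format_error")
  gfp / tof
}

#' Slope of a kinetic fluorescence curve
#'
#' Ordinary least-squares slope of fluorescence against time — the readout
#' of a kinetic enzyme-activity assay read at fixed intervals.
#'
#' @param times Time points (at least 3, not all equal).
#' @param fluorescence Matching readings.
#' @return The fitted slope (fluorescence units per time unit).
#' @export
kinetic_slope <- function(times, fluorescence) {
  if (length(times) < 3 || length(times) != length(fluorescence)) {
    stop_gsc("need >= 3 matched (time, fluorescence) points",
             "gscsoma_format_error")
  }
  if (var(times) == 0) {
    stop_gsc("time points are constant: slope undefined", "gscsoma_format_error")
  }
  unname(stats::cov(times, fluorescence) / var(times))
}
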