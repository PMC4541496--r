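test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # all deaths at distinct times: S drops by 1/n at each
  km <- km_estimate(tibble::tibble(time_days = c(1, 2, 3), event = TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: S stays at 1 (no death events at any time)
  km_c <- km_estimate(tibble::tibble(time_days = c(1, 2, 3), event = FALSE))
  expect_true(all(km_c$survival == 1))
  # mixed censoring, hand-computed product over risk sets:
  # deaths at 2 (5 at risk), 4 (3 at risk), 5 (1 at risk); censored at 3, 4+
  cohort <- tibble::tibble(time_days = c(2, 3, 4, 4, 5),
                           event = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  km_m <- km_estimate(cohort)
  surv_at <- function(t) km_m$survival[max(which(km_m$time <= t))]
  expect_equal(surv_at(2), 4 / 5)
  expect_equal(surv_at(4), 4 / 5 * 2 / 3)
  expect_equal(surv_at(5), 0)
  # KM is non-increasing and starts from 1
  expect_true(all(diff(km_m$survival) <= 0))
  expect_lte(km_m$survival[1], 1)
  expect_error(km_estimate(tibble::tibble(time_days = numeric(), event = logical())),
               class = "gscsoma_format_error")
})

test_that("log-rank is null for identical groups and matches a permutation oracle", {
  base <- tibble::tibble(time_days = c(3, 5, 7, 9, 11),
                         event = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  dup <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                          dplyr::mutate(base, group = "B"))
  res <- logrank_test(dup, "A", "B")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # permutation oracle on a 40-animal two-group fixture
  cfg <- survival_sim_config(
    tibble::tibble(genotype = c("WT", "GSC-"), rnai = "vector",
                   mean_lifespan = c(14, 19), n = 20),
    censor_prob = 0.1, seed = 23)
  cohort <- simulate_survival_cohort(cfg)
  res2 <- logrank_test(cohort, "WT/vector", "GSC-/vector")
  grp <- cohort$group == "WT/vector"
  obs <- logrank_chisq_oracle(cohort$time_days, cohort$event, grp)
  expect_equal(res2$chisq, obs, tolerance = 1e-8)
  set.seed(1)
  perm_stats <- replicate(10000, {
    g <- sample(grp)
    logrank_chisq_oracle(cohort$time_days, cohort$event, g)
  })
  p_perm <- mean(perm_stats >= obs)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 10000) + 1e-4
  expect_lt(abs(res2$p_value - p_perm), 4 * mc_se + 0.01)
  expect_error(logrank_test(dplyr::mutate(dup, event = FALSE), "A", "B"),
               class = "gscsoma_format_error")
})

test_that("percent extension reproduces the printed lifespan table cells", {
  expect_equal(percent_extension(19.94, 15.40), 29.48)
  expect_equal(percent_extension(22.46, 13.99), 60.54)
  expect_equal(percent_extension(10, 10), 0)
  expect_error(percent_extension(10, 0), class = "gscsoma_format_error")
  # every extension cell in both summary tables, recomputed from the
  # printed means, agrees with the printed percentage to the precision the
  # printed (rounded) means can support
  for (tab in list(lifespan_table(), stress_table())) {
    re <- recompute_extensions(tab)
    expect_true(all(abs(re$computed_ext - re$printed_ext) <= re$printed_tolerance))
  }
  # most cells agree to 2 decimals exactly
  re <- recompute_extensions(lifespan_table())
  expect_gte(mean(abs(re$computed_ext - re$printed_ext) < 0.005), 0.8)
  # reciprocal relation: (1 + ea/100)(1 + eb/100) = 1
  ea <- percent_extension(19.94, 15.40)
  eb <- percent_extension(15.40, 19.94)
  expect_equal((1 + ea / 100) * (1 + eb / 100), 1, tolerance = 1e-4)
})

test_that("summary-cell ANOVA equals raw-data ANOVA on balanced designs", {
  set.seed(33)
  n <- 12
  raw <- tidyr::expand_grid(factor1 = c("wt", "mut"), factor2 = c("ctrl", "trt"),
                            rep = seq_len(n))
  raw$y <- 15 + 3 * (raw$factor1 == "mut") + 2 * (raw$factor2 == "trt") +
    1.5 * (raw$factor1 == "mut") * (raw$factor2 == "trt") + rnorm(nrow(raw), 0, 2)
  cells <- dplyr::summarise(
    dplyr::group_by(raw, factor1, factor2),
    mean = mean(y), sem = sd(y) / sqrt(dplyr::n()), n = dplyr::n(),
    .groups = "drop")
  mine <- anova2_from_summary(cells)
  ref <- anova(stats::aov(y ~ factor1 * factor2, data = raw))
  expect_equal(mine$F_interaction, ref["factor1:factor2", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$p_interaction, ref["factor1:factor2", "Pr(>F)"],
               tolerance = 1e-10)
  expect_equal(mine$F_factor1, ref["factor1", "F value"], tolerance = 1e-10)
  expect_equal(mine$df_error, ref["Residuals", "Df"])
})

test_that("additive or equal cell means give a zero interaction", {
  cells <- tibble::tibble(factor1 = c("a", "a", "b", "b"),
                          factor2 = c("x", "y", "x", "y"),
                          mean = c(10, 12, 14, 16), sem = 0.5, n = 20)
  expect_equal(anova2_from_summary(cells)$F_interaction, 0, tolerance = 1e-12)
  cells$mean <- 11
  out <- anova2_from_summary(cells)
  expect_equal(out$F_interaction, 0, tolerance = 1e-12)
  expect_equal(out$p_interaction, 1)
  expect_error(anova2_from_summary(dplyr::mutate(cells, n = 1)),
               class = "gscsoma_format_error")
})

test_that("the lifespan interaction replicates the published direction", {
  # composite 25C cohort: the ablation extends lifespan in the skn-1(+)
  # background far more than in the skn-1(-) background
  t1 <- dplyr::filter(lifespan_table(), set == "C1")
  cells <- tibble::tibble(factor1 = t1$glp1, factor2 = t1$skn1,
                          mean = t1$mean, sem = t1$sem, n = t1$n_events)
  out <- anova2_from_summary(cells)
  expect_lt(out$p_interaction, 0.0001)   # table prints "<0.0001"
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04))
  set.seed(8)
  p <- runif(20)
  adj <- holm_sidak_adjust(p)
  # direct formula oracle
  o <- order(p)
  expected <- cummax(1 - (1 - p[o])^(20 - seq_len(20) + 1))[order(o)]
  expect_equal(adj, expected)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(holm_sidak_adjust(c(0.1, -0.2)), class = "gscsoma_format_error")
})

test_that("chi-squared scoring matches closed forms and brute force", {
  identical_rows <- tibble::tibble(group = c("a", "b"),
                                   high = c(10, 10), medium = c(5, 5),
                                   low = c(2, 2))
  res <- chi2_score_test(identical_rows)
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)
  # 2x2 closed form N(ad - bc)^2 / (row and column products)
  m <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(chi2_score_test(m)$chisq, 20)
  # random tables vs direct sum((O - E)^2 / E)
  set.seed(14)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi2_score_test(tab)$chisq, sum((tab - e)^2 / e))
    expect_equal(chi2_score_test(tab)$df, 2)
  }
  expect_error(chi2_score_test(matrix(c(0, 0, 1, 2), 2)),
               class = "gscsoma_format_error")
})

test_that("fluorescence normalization and kinetic slopes are exact", {
  expect_equal(copas_normalize(1000, 200), 5)
  expect_equal(copas_normalize(0, 7), 0)
  expect_equal(copas_normalize(3 * 1000, 3 * 200), 5)  # scale invariance
  expect_error(copas_normalize(10, 0), class = "gscsoma_format_error")
  t <- seq(0, 60, by = 3)
  expect_equal(kinetic_slope(t, 2 * t + 1), 2)
  expect_equal(kinetic_slope(t, rep(5, length(t))), 0)
  # noisy line vs the covariance/variance closed form
  set.seed(3)
  y <- 1.7 * t + rnorm(length(t))
  expect_equal(kinetic_slope(t, y),
               sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2))
  expect_error(kinetic_slope(c(1, 1, 1), c(1, 2, 3)),
               class = "gscsoma_format_error")
})
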