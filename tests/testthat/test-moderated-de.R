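two_group_design <- function(n_per = 3) {
  d <- cbind(A = rep(c(1, 0), each = n_per), B = rep(c(0, 1), each = n_per))
  rownames(d) <- paste0("s", seq_len(2 * n_per))
  d
}

test_that("noiseless data is fit exactly with zero residual variance", {
  design <- two_group_design()
  beta <- rbind(c(1, 3), c(-2, 0.5))
  E <- beta %*% t(design)
  fit <- fit_gene_models(make_wle(E, design))
  expect_equal(unname(fit$coefficients), unname(beta))
  expect_equal(fit$sigma2, c(0, 0))
  expect_equal(fit$df_residual, c(4, 4))
})

test_that("unit weights reproduce ordinary least squares", {
  set.seed(5)
  design <- cbind(intercept = 1, x = rnorm(8), z = rnorm(8))
  E <- matrix(rnorm(5 * 8), 5, 8)
  fit <- fit_gene_models(make_wle(E, design))
  for (g in 1:5) {
    ols <- lm(E[g, ] ~ 0 + design)
    expect_equal(unname(fit$coefficients[g, ]), unname(coef(ols)))
    expect_equal(fit$sigma2[g], summary(ols)$sigma^2)
  }
})

test_that("sample permutation with matching design rows leaves fits unchanged", {
  set.seed(6)
  design <- two_group_design()
  E <- matrix(rnorm(4 * 6), 4, 6)
  w <- matrix(rexp(24) + 0.5, 4, 6)
  perm <- sample(6)
  f1 <- fit_gene_models(make_wle(E, design, w))
  f2 <- fit_gene_models(make_wle(E[, perm], design[perm, ], w[, perm]))
  expect_equal(f1$coefficients, f2$coefficients, ignore_attr = TRUE)
  expect_equal(f1$sigma2, f2$sigma2)
})

test_that("moderated variance is the df-weighted convex combination", {
  fit <- make_gene_fit(sigma2 = c(4, 4), df = 2)
  eb <- empirical_bayes_moderate(fit, d0 = 4, s02 = 1)
  expect_equal(eb$sigma2_moderated, c(2, 2))   # (4*1 + 2*4) / 6
  expect_equal(eb$df_total, c(6, 6))
  # infinite prior df collapses every gene onto the prior variance
  eb_inf <- empirical_bayes_moderate(fit, d0 = Inf, s02 = 1.7)
  expect_equal(eb_inf$sigma2_moderated, c(1.7, 1.7))
  # d0 = 0 leaves the ordinary variances untouched
  eb0 <- empirical_bayes_moderate(fit, d0 = 0, s02 = 1)
  expect_equal(eb0$sigma2_moderated, fit$sigma2)
  # moderated variance always lies between the prior and the observed
  set.seed(2)
  s2 <- rexp(50)
  ebx <- empirical_bayes_moderate(make_gene_fit(s2, df = 3), d0 = 2, s02 = 1)
  expect_true(all(ebx$sigma2_moderated >= pmin(s2, 1) - 1e-12))
  expect_true(all(ebx$sigma2_moderated <= pmax(s2, 1) + 1e-12))
  expect_error(empirical_bayes_moderate(make_gene_fit(c(0, 0), df = 2)),
               class = "gscsoma_degenerate_error")
})

test_that("variance prior is recovered from a known scaled-F hierarchy", {
  # oracle = the generating simulation: s_true^2 ~ d0 s0^2 / chi2(d0),
  # s_g^2 | s_true^2 ~ s_true^2 chi2(d) / d, with d0 = 4, s0^2 = 2
  set.seed(17)
  d0 <- 4; s02 <- 2; d <- 6; n <- 5000
  s_true <- d0 * s02 / stats::rchisq(n, d0)
  s2 <- s_true * stats::rchisq(n, d) / d
  eb <- empirical_bayes_moderate(make_gene_fit(s2, df = d))
  expect_equal(eb$d0, d0, tolerance = 0.15)
  expect_equal(eb$s02, s02, tolerance = 0.15)
  # and the estimates agree with the reference implementation
  ref <- limma::fitFDist(s2, rep(d, n))
  expect_equal(eb$d0, ref$df2, tolerance = 1e-6)
  expect_equal(eb$s02, ref$scale, tolerance = 1e-6)
})

test_that("contrast tests give exact t, p and fold changes", {
  # intercept-only design, n = 4, prior variance forced to 1 with d0 = Inf:
  # t = mean / sqrt(1/4), so mean 1 gives t = 2 and p = 2(1 - Phi(2))
  design <- matrix(1, 4, 1, dimnames = list(paste0("s", 1:4), "mu"))
  E <- rbind(g1 = c(1.3, 0.7, 1.2, 0.8), g2 = rep(0, 4))
  fit <- fit_gene_models(make_wle(E, design))
  eb <- empirical_bayes_moderate(fit, d0 = Inf, s02 = 1)
  ct <- contrast_test(eb, contrast = 1)
  expect_equal(ct$t[1], 2)
  expect_equal(ct$p_value[1], 2 * pnorm(-2))
  # zero contrast estimate: t = 0, p = 1
  expect_equal(ct$t[2], 0)
  expect_equal(ct$p_value[2], 1)
  expect_equal(ct$FC, 2^ct$logFC)
  expect_error(contrast_test(eb, contrast = 0), class = "gscsoma_design_error")
})

test_that("rescaling all weights leaves moderated t and p unchanged", {
  sim <- small_sim(150, seed = 31)
  wle <- voom_transform(cpm_filter(sim$counts))
  ct1 <- contrast_test(
    empirical_bayes_moderate(fit_gene_models(wle), d0 = 0, s02 = 1),
    c("GSC", "WT"))
  wle2 <- wle
  wle2$weights <- wle$weights * 2
  ct2 <- contrast_test(
    empirical_bayes_moderate(fit_gene_models(wle2), d0 = 0, s02 = 1),
    c("GSC", "WT"))
  expect_equal(ct1$t, ct2$t)
  expect_equal(ct1$p_value, ct2$p_value)
})

test_that("d0 = 0 reproduces the ordinary per-gene t-test", {
  sim <- small_sim(200, seed = 13)
  wle <- voom_transform(cpm_filter(sim$counts))
  fit <- fit_gene_models(wle)
  ct <- contrast_test(empirical_bayes_moderate(fit, d0 = 0, s02 = 1),
                      c("GSC", "WT"))
  # oracle: weighted regression per gene via lm(), t for the GSC-WT contrast
  design <- wle$design
  for (g in sample(nrow(wle$E), 10)) {
    lmfit <- lm(wle$E[g, ] ~ 0 + design, weights = wle$weights[g, ])
    est <- coef(lmfit)
    vc <- vcov(lmfit)
    cv <- as.numeric(colnames(design) == "GSC") - as.numeric(colnames(design) == "WT")
    tval <- sum(cv * est) / sqrt(drop(t(cv) %*% vc %*% cv))
    i <- match(rownames(wle$E)[g], ct$gene)
    expect_equal(ct$t[i], tval, tolerance = 1e-8)
  }
})

test_that("Benjamini-Hochberg q-values match the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "gscsoma_format_error")
  # brute-force step-up oracle on random p-values
  set.seed(9)
  p <- runif(200)
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(bh_fdr(p)[o], pmin(q_sorted, 1))
  # invariant to input order
  perm <- sample(m)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
})

test_that("uniform p-values under a global null yield almost no q < 0.05 calls", {
  set.seed(77)
  p <- runif(10000)
  expect_lte(sum(bh_fdr(p) < 0.05), 2)
})
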