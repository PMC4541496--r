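test_that("the min-|t| statistic enforces the sign pattern", {
  expect_equal(min_t_statistic(3, -2), 2)
  expect_equal(min_t_statistic(-3, -2), 0)   # first sign violated
  expect_equal(min_t_statistic(3, 2), 0)     # second sign violated
  expect_equal(min_t_statistic(0, 0), 0)
  expect_equal(min_t_statistic(c(3, -3), c(-2, -2)), c(2, 0))
  # always bounded by min(|t1|, |t2|) and non-negative
  set.seed(4)
  t1 <- rnorm(200); t2 <- rnorm(200)
  T <- min_t_statistic(t1, t2)
  expect_true(all(T >= 0))
  expect_true(all(T <= pmin(abs(t1), abs(t2)) + 1e-12))
  expect_error(min_t_statistic(Inf, 1), class = "gscsoma_format_error")
  # flipped pattern flips which pairs qualify
  expect_equal(min_t_statistic(-3, 2, sign_pattern("-", "+")), 2)
})

test_that("the randomized-t null has 1/4 of its mass above zero", {
  null <- sample_null_distribution(df1 = 6, df2 = 6, n_draws = 4e4, seed = 2)
  frac <- mean(null$null_sorted > 0)
  mc_se <- sqrt(0.25 * 0.75 / 4e4)
  expect_lt(abs(frac - 0.25), 3 * mc_se)
  # seed determinism
  null2 <- sample_null_distribution(df1 = 6, df2 = 6, n_draws = 4e4, seed = 2)
  expect_identical(null$null_sorted, null2$null_sorted)
  expect_warning(sample_null_distribution(6, 6, n_draws = 500, seed = 1),
                 class = "gscsoma_null_warning")
  expect_error(sample_null_distribution(0, 6), class = "gscsoma_config_error")
})

test_that("the infinite-df null matches a direct normal simulation", {
  null <- sample_null_distribution(df1 = Inf, df2 = Inf, n_draws = 2e4, seed = 3)
  # oracle: independent normal draws through the same min/sign definition,
  # written out directly
  set.seed(777)
  z1 <- rnorm(2e4); z2 <- rnorm(2e4)
  keep <- z1 > 0 & z2 < 0
  oracle <- ifelse(keep, pmin(abs(z1), abs(z2)), 0)
  ks <- suppressWarnings(stats::ks.test(null$null_sorted[null$null_sorted > 0],
                                        oracle[oracle > 0]))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical p-values follow the add-one counting rule", {
  null <- structure(list(null_sorted = sort(c(0.5, 1.0, 2.5, 3.0)),
                         n_draws = 4L), class = "null_model")
  expect_equal(empirical_pvalue(2.0, null), 3 / 5)
  expect_equal(empirical_pvalue(0, null), 1)      # every null value >= 0
  expect_equal(empirical_pvalue(10, null), 1 / 5) # beyond the max draw
  # monotone non-increasing in T
  grid <- seq(0, 4, by = 0.25)
  expect_true(all(diff(empirical_pvalue(grid, null)) <= 0))
})

test_that("the screen aligns genes, is deterministic, and rejects mismatches", {
  sim <- small_sim(200, seed = 55)
  de <- run_expression_pipeline(sim)
  scr1 <- run_screen(de$contrasts$gsc_vs_wt, de$contrasts$skn1rnai_vs_gsc,
                     n_draws = 5000, seed = 10)
  scr2 <- run_screen(de$contrasts$gsc_vs_wt, de$contrasts$skn1rnai_vs_gsc,
                     n_draws = 5000, seed = 10)
  expect_identical(tibble::as_tibble(scr1), tibble::as_tibble(scr2))
  # shuffling contrast2's row order changes nothing (genes are matched)
  shuffled <- de$contrasts$skn1rnai_vs_gsc[sample(nrow(de$contrasts$skn1rnai_vs_gsc)), ]
  scr3 <- run_screen(de$contrasts$gsc_vs_wt, shuffled, n_draws = 5000, seed = 10)
  expect_identical(tibble::as_tibble(scr1), tibble::as_tibble(scr3))
  # feeding the same contrast twice can never satisfy the (+,-) pattern
  self <- run_screen(de$contrasts$gsc_vs_wt, de$contrasts$gsc_vs_wt,
                     n_draws = 5000, seed = 10)
  expect_true(all(self$T == 0))
  expect_true(all(self$p_value == 1))
  # gene mismatch errors
  expect_error(run_screen(de$contrasts$gsc_vs_wt,
                          de$contrasts$skn1rnai_vs_gsc[-1, ]),
               class = "gscsoma_format_error")
})

test_that("correlated null draws reflect the design coupling of the contrasts", {
  # sharing the middle group in a balanced cell-means design gives
  # cor(t1, t2) = -0.5 exactly
  d <- condition_design(tibble::tibble(
    sample = paste0("s", 1:9),
    genotype = rep(c("WT", "GSC-", "GSC-"), each = 3),
    rnai = rep(c("vector", "vector", "skn-1"), each = 3),
    replicate = rep(1:3, 3)))
  c1 <- contrast_vector(d, "GSC", "WT")
  c2 <- contrast_vector(d, "GSC_skn1", "GSC")
  expect_equal(gscsoma:::contrast_null_correlation(d, c1, c2), -0.5)
  # with rho = -0.5 the sign event probability rises from 1/4 to
  # 1/4 + asin(1/2)/(2*pi) = 1/3 (orthant probability, closed form)
  null <- sample_null_distribution(Inf, Inf, n_draws = 4e4, seed = 5,
                                   rho = -0.5)
  expect_lt(abs(mean(null$null_sorted > 0) - 1 / 3),
            3 * sqrt(1 / 3 * 2 / 3 / 4e4))
})

test_that("the screen recovers planted skn-1-dependent genes with FDR control", {
  # benchmark background: no compartment, the planted genes are the only
  # true effects, so q < 0.05 should deliver high recall and low FDP
  sim <- simulate_expression_counts(
    screen_benchmark_config(n_genes = 3000, n_planted = 30,
                            library_size = 4e6, seed = 77))
  de <- run_expression_pipeline(sim)
  scr <- run_screen(de$contrasts$gsc_vs_wt, de$contrasts$skn1rnai_vs_gsc,
                    n_draws = 5e4, seed = 1)
  hits <- scr$gene[scr$q_value < 0.05]
  truth <- sim$truth[match(scr$gene, sim$truth$gene), ]
  planted <- truth$gene[truth$class == "skn1_dependent"]
  expect_equal(length(planted), 30)
  expect_gt(mean(planted %in% hits), 0.8)
  expect_lt(mean(!hits %in% planted), 0.15)
})

test_that("composition-driven fold changes demand the fold-change classifiers", {
  # on a gamma = 2/3 background every soma-restricted gene carries a real
  # t1, so screen significance alone over-calls; genes passing the
  # published joint rule (q < 0.05 plus FC > 4 and FC < 0.67) are almost
  # all truly skn-1-dependent
  sim <- simulate_expression_counts(
    sim_config(n_genes = 3000, library_size = 5e6, seed = 7))
  de <- run_expression_pipeline(sim)
  scr <- run_screen(de$contrasts$gsc_vs_wt, de$contrasts$skn1rnai_vs_gsc,
                    n_draws = 5e4, seed = 2)
  sets <- classify_gene_sets(tibble::tibble(
    gene = de$contrasts$gsc_vs_wt$gene,
    fc_gsc_vs_wt = de$contrasts$gsc_vs_wt$FC,
    fc_skn1_vs_gsc = de$contrasts$skn1rnai_vs_gsc$FC,
    p_skn1_vs_gsc = de$contrasts$skn1rnai_vs_gsc$p_value))
  joint <- scr$gene[scr$q_value < 0.05 &
                      sets$SKN1_dependent_GSC[match(scr$gene, sets$gene)]]
  truth <- sim$truth[match(joint, sim$truth$gene), ]
  expect_gt(length(joint), 10)
  expect_gt(mean(truth$class == "skn1_dependent"), 0.9)
})

test_that("gene-set classification applies the published threshold rules", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    fc_gsc_vs_wt = c(6, 6, 4.0, 4.5),
    fc_skn1_vs_gsc = c(0.5, 0.8, 0.5, 0.67),
    p_skn1_vs_gsc = c(0.01, 0.01, 0.01, 0.01))
  sets <- classify_gene_sets(tab)
  expect_equal(sets$GSC_up4, c(TRUE, TRUE, FALSE, TRUE))   # strict > 4
  expect_equal(sets$GSC_up5, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sets$SKN1_up_GSC, c(TRUE, FALSE, TRUE, FALSE)) # strict < 0.67
  expect_equal(sets$SKN1_dependent_GSC, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(sets$SKN1_up_WT)))
  # with the WT-background contrast supplied the WT set is populated
  tab$fc_skn1_vs_wt <- c(0.5, 0.5, 0.9, 0.5)
  tab$p_skn1_vs_wt <- c(0.01, 0.2, 0.01, 0.01)
  sets2 <- classify_gene_sets(tab)
  expect_equal(sets2$SKN1_up_WT, c(TRUE, FALSE, FALSE, TRUE))
  # subset invariants on random tables
  set.seed(12)
  rnd <- tibble::tibble(gene = paste0("g", 1:500),
                        fc_gsc_vs_wt = exp(rnorm(500)),
                        fc_skn1_vs_gsc = exp(rnorm(500)),
                        p_skn1_vs_gsc = runif(500))
  s <- classify_gene_sets(rnd)
  expect_true(all(!s$GSC_up5 | s$GSC_up4))
  expect_true(all(!s$SKN1_dependent_GSC | s$GSC_up4))
  expect_true(all(!s$SKN1_dependent_GSC | s$SKN1_up_GSC))
})

test_that("gene-set membership files are newline-delimited id lists", {
  tab <- tibble::tibble(gene = c("a", "b"), fc_gsc_vs_wt = c(6, 2),
                        fc_skn1_vs_gsc = c(0.5, 0.9),
                        p_skn1_vs_gsc = c(0.01, 0.5))
  dir <- withr::local_tempdir()
  write_gene_sets(classify_gene_sets(tab), dir)
  expect_equal(readLines(file.path(dir, "GSC_up4.txt")), "a")
  expect_equal(readLines(file.path(dir, "SKN1_dependent_GSC.txt")), "a")
})
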