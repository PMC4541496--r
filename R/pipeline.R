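#' One-call differential-expression pipeline
#'
#' Chains the standard stages on a three-condition count experiment:
#' CPM filter, quantile-normalized precision-weighted log-expression,
#' gene-wise weighted fits, empirical-Bayes moderation, and the two
#' contrasts the dependency screen consumes (ablated vs WT, `skn-1` RNAi vs
#' ablated; plus ablated+RNAi vs WT when requested).
#'
#' @param x A [count_matrix()] or a `gsc_sim` (its counts are used).
#' @param min_cpm,min_samples Expression-filter settings ([cpm_filter()]).
#' @param quantile_normalize Passed to [voom_transform()].
#' @param with_wt_contrast Also compute the ablated+RNAi vs WT contrast.
#' @return A list of class `gsc_de`: `filtered` (count matrix), `wle`,
#'   `fit`, `ebayes`, and `contrasts` (named list of `contrast_result`
#'   tibbles: `gsc_vs_wt`, `skn1rnai_vs_gsc`, optionally `skn1rnai_vs_wt`).
#' @export
#' @examples
#' sim <- simulate_expression_counts(sim_config(n_genes = 400, library_size = 2e5))
#' de <- run_expression_pipeline(sim)
#' head(de$contrasts$gsc_vs_wt)
run_expression_pipeline <- function(x, min_cpm = 1, min_samples = 2,
                                    quantile_normalize = TRUE,
                                    with_wt_contrast = FALSE) {
  if (inherits(x, "gsc_sim")) x <- x$counts
  stopifnot(inherits(x, "count_matrix"))
  filtered <- cpm_filter(x, min_cpm = min_cpm, min_samples = min_samples)
  wle <- voom_transform(filtered, quantile_normalize = quantile_normalize)
  fit <- fit_gene_models(wle)
  eb <- empirical_bayes_moderate(fit)
  contrasts <- list(
    gsc_vs_wt = contrast_test(eb, c("GSC", "WT")),
    skn1rnai_vs_gsc = contrast_test(eb, c("GSC_skn1", "GSC"))
  )
  if (with_wt_contrast) {
    contrasts$skn1rnai_vs_wt <- contrast_test(eb, c("GSC_skn1", "WT"))
  }
  structure(list(filtered = filtered, wle = wle, fit = fit, ebayes = eb,
                 contrasts = contrasts),
            class = "gsc_de")
}

#' @export
print.gsc_de <- function(x, ...) {
  cat("<gsc_de>", nrow(x$filtered$counts), "genes after filtering;",
      "contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  print(x$ebayes)
  invisible(x)
}

#' Write per-contrast results as TSV
#'
#' One `results_<contrast>.tsv` per contrast: gene, logFC, FC, t, p, q.
#'
#' @param de A `gsc_de` from [run_expression_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_de_results <- function(de, dir) {
  stopifnot(inherits(de, "gsc_de"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(de$contrasts, function(tab, nm) {
    path <- file.path(dir, paste0("results_", nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tab), path)
    path
  })
  invisible(paths)
}
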