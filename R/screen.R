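#' Sign pattern for the two-contrast dependency screen
#'
#' The screen looks for genes whose expression goes up after germline
#' ablation (contrast 1: ablated vs WT, required sign `+`) and back down
#' under `skn-1` RNAi in the ablated background (contrast 2, required sign
#' `-`). Other patterns can be tested by flipping either entry.
#'
#' @param t1,t2 Required sign of each contrast's t-statistic, `"+"` or `"-"`.
#' @return A `sign_pattern` object.
#' @export
sign_pattern <- function(t1 = "+", t2 = "-") {
  if (!t1 %in% c("+", "-") || !t2 %in% c("+", "-")) {
    stop_gsc('pattern entries must be "+" or "-"', "gscsoma_config_error")
  }
  structure(list(s1 = if (t1 == "+") 1 else -1,
                 s2 = if (t2 == "+") 1 else -1),
            class = "sign_pattern")
}

#' Minimum-absolute-t dependency statistic
#'
#' For each gene, if both t-statistics carry the required signs the
#' statistic is the smaller of their absolute values; a gene violating the
#' sign pattern cannot be called and gets 0. This is an intersection-union
#' construction: the statistic is large only when both effects are present
#' in the required directions.
#'
#' @param t1,t2 Finite t-statistic vectors (same length).
#' @param pattern A [sign_pattern()]; default up-then-down (`+`, `-`).
#' @return Non-negative statistic vector, `T <= min(|t1|, |t2|)`.
#' @export
#' @examples
#' min_t_statistic(3, -2)           # 2
#' min_t_statistic(-3, -2)          # 0: first sign violated
min_t_statistic <- function(t1, t2, pattern = sign_pattern()) {
  if (length(t1) != length(t2)) {
    stop_gsc("t1 and t2 must have the same length", "gscsoma_format_error")
  }
  if (any(!is.finite(t1)) || any(!is.finite(t2))) {
    stop_gsc("t-statistics must be finite", "gscsoma_format_error")
  }
  ok <- (sign(t1) == pattern$s1) & (sign(t2) == pattern$s2)
  ifelse(ok, pmin(abs(t1), abs(t2)), 0)
}

#' Randomized-t null distribution for the min-|t| statistic
#'
#' Draws independent pairs of t-variates at the given degrees of freedom,
#' applies [min_t_statistic()] with the pattern, and stores the resulting
#' null sample. Because the two signs agree with the pattern with
#' probability 1/4 under independence, three quarters of the null mass sits
#' at exactly 0 — which is what makes the empirical p-values conservative
#' for sign-violating genes.
#'
#' @param df1,df2 Degrees of freedom for the two simulated t-statistics
#'   (`Inf` gives normal draws).
#' @param n_draws Number of null draws (at least 1000; the default 1e5
#'   resolves p-values down to 1e-5).
#' @param seed Integer seed.
#' @param pattern A [sign_pattern()].
#' @param rho Correlation of the simulated pair. The default 0 draws
#'   independent t-variates. When the two contrasts share a condition (as
#'   ablated-vs-WT and RNAi-vs-ablated share the ablated group) their
#'   t-statistics are correlated by design even under the null; passing the
#'   design-implied `rho` draws a correlated normal pair divided by a
#'   shared chi-square scale at the average df — the joint null of two
#'   contrasts computed from one gene's fit.
#' @return A `null_model` object: sorted null statistics plus the
#'   generating parameters.
#' @export
sample_null_distribution <- function(df1, df2, n_draws = 1e5, seed = 1L,
                                     pattern = sign_pattern(), rho = 0) {
  if (df1 <= 0 || df2 <= 0) {
    stop_gsc("degrees of freedom must be positive", "gscsoma_config_error")
  }
  if (abs(rho) >= 1) {
    stop_gsc("`rho` must lie in (-1, 1)", "gscsoma_config_error")
  }
  if (n_draws < 1000) {
    warn("fewer than 1000 null draws: empirical p-values will be coarse",
         class = "gscsoma_null_warning")
  }
  local_seed(seed, {
    if (rho == 0) {
      t1 <- if (is.infinite(df1)) rnorm(n_draws) else rt(n_draws, df1)
      t2 <- if (is.infinite(df2)) rnorm(n_draws) else rt(n_draws, df2)
    } else {
      df <- (df1 + df2) / 2
      z1 <- rnorm(n_draws)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_draws)
      s <- if (is.infinite(df)) 1 else sqrt(stats::rchisq(n_draws, df) / df)
      t1 <- z1 / s
      t2 <- z2 / s
    }
    null_t <- sort(min_t_statistic(t1, t2, pattern))
    structure(list(null_sorted = null_t, df1 = df1, df2 = df2, rho = rho,
                   n_draws = as.integer(n_draws), seed = as.integer(seed),
                   pattern = pattern),
              class = "null_model")
  })
}

# Design-implied null correlation between two contrasts sharing a fit:
# rho = c1' (X'X)^-1 c2 / sqrt((c1' (X'X)^-1 c1)(c2' (X'X)^-1 c2)).
contrast_null_correlation <- function(design, c1, c2) {
  xtxi <- chol2inv(chol(crossprod(design)))
  drop(t(c1) %*% xtxi %*% c2) /
    sqrt(drop(t(c1) %*% xtxi %*% c1) * drop(t(c2) %*% xtxi %*% c2))
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model>", x$n_draws, "draws; df = (",
      format(x$df1, digits = 4), ",", format(x$df2, digits = 4), "); P(T>0) =",
      format(mean(x$null_sorted > 0), digits = 3), "\n")
  invisible(x)
}

#' Empirical p-value against a stored null
#'
#' `p = (1 + #\{null >= T\}) / (1 + n_draws)`: the add-one rule keeps p in
#' `(0, 1]` and makes it exact under exchangeability.
#'
#' @param T Observed statistic(s), non-negative.
#' @param null A `null_model` from [sample_null_distribution()].
#' @return Empirical p-values, monotone non-increasing in `T`.
#' @export
empirical_pvalue <- function(T, null) {
  stopifnot(inherits(null, "null_model"))
  n <- length(null$null_sorted)
  ge <- n - findInterval(T, null$null_sorted, left.open = TRUE)
  (1 + ge) / (1 + n)
}

#' Run the SKN-1-dependency screen over two contrasts
#'
#' Aligns the two contrast tables by gene, forms the min-|t| statistic under
#' the sign pattern, computes empirical p-values against a randomized-t null
#' at the pooled moderated degrees of freedom (median of each contrast's
#' total df, unless a null is supplied), and controls the FDR by
#' Benjamini-Hochberg over all screened genes — sign-violating genes stay in
#' the denominator with `T = 0`.
#'
#' By default the null pairs are drawn with the correlation the design
#' imposes on the two contrasts (`-0.5` when they share the ablated group
#' in a balanced cell-means design) and a shared variance scale, since both
#' t-statistics come from the same gene fit; an independent-pairs null
#' (`null_correlation = "independent"`) is anti-conservative for this
#' design and kept only for comparison.
#'
#' @param contrast1 `contrast_result` for ablated vs WT.
#' @param contrast2 `contrast_result` for `skn-1` RNAi vs ablated.
#' @param pattern A [sign_pattern()].
#' @param null Optional pre-computed `null_model`; otherwise drawn here.
#' @param null_correlation `"design"` (default) derives the null pair
#'   correlation from the contrasts' design; `"independent"` draws
#'   uncorrelated pairs; a number in (-1, 1) sets it directly.
#' @param n_draws,seed Passed to [sample_null_distribution()] when `null`
#'   is not supplied.
#' @return A `dependency_screen` tibble: `gene`, `t1`, `t2`, `T`,
#'   `sign_ok`, `p_value`, `q_value`; the null model is attached as the
#'   `"null"` attribute.
#' @export
run_screen <- function(contrast1, contrast2, pattern = sign_pattern(),
                       null = NULL, null_correlation = "design",
                       n_draws = 1e5, seed = 1L) {
  if (!setequal(contrast1$gene, contrast2$gene) ||
      nrow(contrast1) != nrow(contrast2)) {
    stop_gsc("the two contrasts must cover the same genes", "gscsoma_format_error")
  }
  contrast2 <- contrast2[match(contrast1$gene, contrast2$gene), ]
  if (is.null(null)) {
    rho <- if (identical(null_correlation, "independent")) 0
    else if (is.numeric(null_correlation)) null_correlation
    else {
      design <- attr(contrast1, "design")
      c1 <- attr(contrast1, "contrast")
      c2 <- attr(contrast2, "contrast")
      if (is.null(design) || is.null(c1) || is.null(c2)) {
        stop_gsc(paste("contrasts carry no design information:",
                       "pass a numeric `null_correlation` or a `null`"),
                 "gscsoma_design_error")
      }
      # clamp: identical contrasts give rho = 1, degenerate but harmless
      # since no such pair can satisfy an opposite-sign pattern
      max(-0.99, min(0.99, contrast_null_correlation(design, c1, c2)))
    }
    null <- sample_null_distribution(df1 = median(contrast1$df_total),
                                     df2 = median(contrast2$df_total),
                                     n_draws = n_draws, seed = seed,
                                     pattern = pattern, rho = rho)
  }
  T <- min_t_statistic(contrast1$t, contrast2$t, pattern)
  p <- empirical_pvalue(T, null)
  out <- tibble::tibble(gene = contrast1$gene,
                        t1 = contrast1$t, t2 = contrast2$t,
                        T = T, sign_ok = T > 0,
                        p_value = p, q_value = bh_fdr(p))
  attr(out, "null") <- null
  class(out) <- c("dependency_screen", class(out))
  out
}

#' @describeIn run_screen Scatter of the two t-statistics, screen hits
#'   (q below `q_threshold`) highlighted.
#' @param object,... Method arguments.
#' @param q_threshold FDR threshold used for highlighting.
#' @export
autoplot.dependency_screen <- function(object, q_threshold = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$hit <- d$q_value < q_threshold
  ggplot2::ggplot(d, ggplot2::aes(.data$t1, .data$t2, color = .data$hit)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "t (ablated vs WT)", y = "t (skn-1 RNAi vs ablated)",
                  color = paste0("q < ", q_threshold))
}

#' Published-style gene-set classification on fold changes
#'
#' Reproduces the study's threshold rules on linear-scale fold changes
#' (strict inequalities throughout):
#' * `GSC_up4` — FC > 4 in the ablated-vs-WT comparison;
#' * `GSC_up5` — FC > 5 (a subset of `GSC_up4`);
#' * `SKN1_up_GSC` — FC < 0.67 under `skn-1` RNAi in the ablated
#'   background with p < 0.05 (a 33% reduction and FC < 0.67 coincide:
#'   1 - 0.33 = 0.67);
#' * `SKN1_up_WT` — same rule in the WT background, populated only when
#'   that contrast is supplied;
#' * `SKN1_dependent_GSC` — `GSC_up4` and `SKN1_up_GSC` jointly.
#'
#' @param fc_table Tibble with columns `gene`, `fc_gsc_vs_wt`,
#'   `fc_skn1_vs_gsc`, `p_skn1_vs_gsc`, and optionally `fc_skn1_vs_wt` +
#'   `p_skn1_vs_wt`.
#' @param fc_up,fc_up_strict Upregulation thresholds (4 and 5).
#' @param fc_down Knockdown threshold (0.67).
#' @param p_max p-value cutoff for the knockdown rule (0.05).
#' @return A `gene_sets` tibble: `gene` plus one logical column per set.
#' @export
classify_gene_sets <- function(fc_table, fc_up = 4, fc_up_strict = 5,
                               fc_down = 0.67, p_max = 0.05) {
  needed <- c("gene", "fc_gsc_vs_wt", "fc_skn1_vs_gsc", "p_skn1_vs_gsc")
  if (!all(needed %in% names(fc_table))) {
    stop_gsc(paste("`fc_table` needs columns:", paste(needed, collapse = ", ")),
             "gscsoma_format_error")
  }
  out <- tibble::tibble(
    gene = fc_table$gene,
    GSC_up4 = fc_table$fc_gsc_vs_wt > fc_up,
    GSC_up5 = fc_table$fc_gsc_vs_wt > fc_up_strict,
    SKN1_up_GSC = fc_table$fc_skn1_vs_gsc < fc_down &
      fc_table$p_skn1_vs_gsc < p_max
  )
  if (all(c("fc_skn1_vs_wt", "p_skn1_vs_wt") %in% names(fc_table))) {
    out$SKN1_up_WT <- fc_table$fc_skn1_vs_wt < fc_down &
      fc_table$p_skn1_vs_wt < p_max
  } else {
    out$SKN1_up_WT <- NA
  }
  out$SKN1_dependent_GSC <- out$GSC_up4 & out$SKN1_up_GSC
  class(out) <- c("gene_sets", class(out))
  out
}

#' Write gene-set memberships as plain-text gene lists
#'
#' One newline-delimited id file per set, named `<set>.txt`.
#'
#' @param sets A `gene_sets` tibble from [classify_gene_sets()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_gene_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set_cols <- setdiff(names(sets), "gene")
  paths <- character()
  for (s in set_cols) {
    member <- sets$gene[which(sets[[s]])]
    path <- file.path(dir, paste0(s, ".txt"))
    writeLines(member, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
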