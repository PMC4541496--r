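#' Gene-wise weighted least-squares fits
#'
#' Fits the design to every gene's log-expression by weighted least squares
#' using the per-observation precision weights, returning coefficients,
#' unscaled covariance, residual variance and residual degrees of freedom —
#' the raw material for empirical-Bayes moderation.
#'
#' @param wle A `weighted_logexpr` from [voom_transform()].
#' @param design Optional design matrix; defaults to the one stored in `wle`.
#' @return A `gene_fit` object: `coefficients` (genes x p),
#'   `cov_unscaled` (genes x p x p array of `(X'WX)^-1`), `sigma2`
#'   (residual variances), `df_residual`, `design`, `genes`.
#' @export
fit_gene_models <- function(wle, design = NULL) {
  stopifnot(inherits(wle, "weighted_logexpr"))
  design <- design %||% wle$design
  y <- wle$E
  w <- wle$weights
  n <- ncol(y)
  p <- ncol(design)
  if (qr(design)$rank < p) {
    stop_gsc("design matrix is rank deficient", "gscsoma_design_error")
  }
  if (n <= p) {
    stop_gsc("fewer samples than model parameters", "gscsoma_design_error")
  }
  g <- nrow(y)
  coef <- matrix(NA_real_, g, p, dimnames = list(rownames(y), colnames(design)))
  covu <- array(NA_real_, c(g, p, p))
  sigma2 <- numeric(g)
  for (i in seq_len(g)) {
    sw <- sqrt(w[i, ])
    xs <- design * sw
    ys <- y[i, ] * sw
    a <- crossprod(xs)
    r <- chol(a)
    ainv <- chol2inv(r)
    b <- drop(ainv %*% crossprod(xs, ys))
    resid <- ys - drop(xs %*% b)
    coef[i, ] <- b
    covu[i, , ] <- ainv
    sigma2[i] <- sum(resid^2) / (n - p)
  }
  structure(list(coefficients = coef, cov_unscaled = covu, sigma2 = sigma2,
                 df_residual = rep(n - p, g), design = design,
                 genes = rownames(y)),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit>", length(x$genes), "genes;",
      ncol(x$coefficients), "coefficients;",
      "residual df", x$df_residual[1], "\n")
  invisible(x)
}

#' @export
tidy.gene_fit <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$genes, times = ncol(x$coefficients)),
    term = rep(colnames(x$coefficients), each = length(x$genes)),
    estimate = as.vector(x$coefficients)
  )
}

#' @export
glance.gene_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 n_coef = ncol(x$coefficients),
                 df_residual = x$df_residual[1])
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks each gene's residual variance toward a common prior by treating
#' the gene variances as draws from a scaled-F hierarchy. When the prior
#' parameters are not supplied they are estimated by matching moments of
#' `log(s_g^2)` against the theoretical log-F distribution (digamma /
#' trigamma closed forms). The moderated variance is the degrees-of-freedom-
#' weighted convex combination `(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`; an
#' infinite `d0` collapses every gene to `s0^2`, while `d0 = 0` leaves the
#' ordinary variances untouched.
#'
#' @param fit A `gene_fit` from [fit_gene_models()].
#' @param d0 Optional prior degrees of freedom (`Inf` and 0 allowed).
#' @param s02 Optional prior variance (> 0).
#' @return An `ebayes_fit` object: `d0`, `s02`, `sigma2_moderated`,
#'   `df_total` (`d0 + d_g`), plus the originating `gene_fit` pieces needed
#'   downstream.
#' @export
empirical_bayes_moderate <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "gene_fit"))
  s2 <- fit$sigma2
  df <- fit$df_residual
  if (length(s2) < 2) {
    stop_gsc("need at least two genes for moderation", "gscsoma_degenerate_error")
  }
  if (all(s2 == 0)) {
    stop_gsc("all residual variances are zero: nothing to moderate",
             "gscsoma_degenerate_error")
  }
  if (is.null(d0) || is.null(s02)) {
    est <- estimate_variance_prior(s2, df)
    d0 <- d0 %||% est$d0
    s02 <- s02 %||% est$s02
  }
  if (d0 < 0 || s02 <= 0) {
    stop_gsc("prior df must be >= 0 and prior variance > 0", "gscsoma_config_error")
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + df * s2) / (d0 + df)
  structure(list(d0 = d0, s02 = s02, sigma2_moderated = s2_mod,
                 df_total = d0 + df, fit = fit),
            class = "ebayes_fit")
}

# Closed-form moment estimator for the scaled-F variance prior: works on
# log(s2), whose mean/variance under the hierarchy are digamma/trigamma
# expressions in (d0, s0^2). Genes with zero variance or zero df are left
# out of estimation but still moderated by the caller.
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  s2 <- s2[ok]
  df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(x) = y; monotone decreasing so the iteration
# from limma's classic starting point converges quickly.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat("<ebayes_fit> prior df d0 =", format(x$d0, digits = 4),
      "; prior variance s0^2 =", format(x$s02, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.ebayes_fit <- function(x, ...) {
  tibble::tibble(gene = x$fit$genes,
                 sigma2 = x$fit$sigma2,
                 sigma2_moderated = x$sigma2_moderated,
                 df_total = x$df_total)
}

#' @export
glance.ebayes_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s02 = x$s02, n_genes = length(x$fit$genes))
}

#' Moderated t-test of a contrast
#'
#' Tests `c' beta = 0` per gene with the moderated variance: the statistic is
#' the contrast estimate over its unscaled standard error times the
#' moderated residual standard deviation, referred to a t distribution on
#' `d0 + d_g` degrees of freedom (normal when `d0` is infinite). Fold
#' changes are reported on both the log2 and the linear scale, with
#' Benjamini-Hochberg q-values across genes.
#'
#' @param eb An `ebayes_fit` from [empirical_bayes_moderate()].
#' @param contrast Numeric contrast vector over the design coefficients
#'   (see [contrast_vector()]), or a pair `c(treatment, control)` of design
#'   column names.
#' @param name Optional contrast name recorded in the result.
#' @return A `contrast_result` tibble: `gene`, `logFC`, `FC`, `t`,
#'   `df_total`, `p_value`, `q_value`.
#' @export
contrast_test <- function(eb, contrast, name = NULL) {
  stopifnot(inherits(eb, "ebayes_fit"))
  fit <- eb$fit
  if (is.character(contrast) && length(contrast) == 2) {
    name <- name %||% paste0(contrast[1], "_vs_", contrast[2])
    contrast <- contrast_vector(fit$design, contrast[1], contrast[2])
  }
  if (length(contrast) != ncol(fit$coefficients)) {
    stop_gsc("contrast length does not match the design coefficients",
             "gscsoma_design_error")
  }
  if (all(contrast == 0)) {
    stop_gsc("contrast vector is all zero", "gscsoma_design_error")
  }
  logfc <- drop(fit$coefficients %*% contrast)
  # u_g^2 = c' (X'WX)^-1 c per gene, from the stored unscaled covariance
  u2 <- numeric(length(logfc))
  for (j in seq_along(contrast)) {
    for (k in seq_along(contrast)) {
      if (contrast[j] != 0 && contrast[k] != 0) {
        u2 <- u2 + contrast[j] * contrast[k] * fit$cov_unscaled[, j, k]
      }
    }
  }
  se <- sqrt(u2 * eb$sigma2_moderated)
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * pt(-abs(tstat), df = eb$df_total)
  out <- tibble::tibble(gene = fit$genes, logFC = logfc, FC = 2^logfc,
                        t = tstat, df_total = eb$df_total,
                        p_value = p, q_value = bh_fdr(p))
  attr(out, "contrast") <- contrast
  attr(out, "contrast_name") <- name
  attr(out, "design") <- fit$design
  class(out) <- c("contrast_result", class(out))
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_gsc("p-values must lie in [0, 1]", "gscsoma_format_error")
  }
  p.adjust(pvals, method = "BH")
}
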