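#' Filter genes on counts per million
#'
#' Keeps genes with at least `min_cpm` counts per million in at least
#' `min_samples` samples; everything else is removed before normalization.
#' The filter is idempotent.
#'
#' @param x A [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 2).
#' @return A filtered [count_matrix()].
#' @export
#' @examples
#' sim <- simulate_expression_counts(sim_config(n_genes = 300, library_size = 5e4))
#' dim(cpm_filter(sim$counts))
cpm_filter <- function(x, min_cpm = 1, min_samples = 2) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(cpm(x) >= min_cpm) >= min_samples
  count_matrix(x$counts[keep, , drop = FALSE], x$samples)
}

#' Quantile-normalize a matrix across columns
#'
#' Forces every column to share the same empirical distribution (the mean of
#' the per-column sorted values). Tied values within a column receive the
#' average of the reference values at their tied ranks.
#'
#' @param x Numeric matrix (genes x samples).
#' @return Matrix of the same shape with identical sorted columns.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    ave(v, match(col, col), FUN = mean)
  })
}

#' Log-CPM transform with precision weights
#'
#' Converts filtered counts to `log2` counts per million with a 0.5-count /
#' +1-library offset, optionally quantile-normalizes across samples, then
#' estimates the mean-variance trend of the log-counts: gene-wise linear
#' fits on the design give residual standard deviations, a lowess curve of
#' `sqrt(sd)` against average log-count is fit, and each observation's
#' weight is the predicted `sqrt(sd)` at its fitted log-count raised to the
#' power -4 (i.e. the reciprocal of its predicted variance).
#'
#' @param x A filtered [count_matrix()].
#' @param design Design matrix (rows = samples); defaults to the cell-means
#'   design on the sample sheet's condition.
#' @param quantile_normalize Logical; normalize the log-CPM across samples
#'   before trend estimation.
#' @param span Lowess span for the mean-variance trend.
#' @return A `weighted_logexpr` object: list with `E` (log2-CPM matrix),
#'   `weights` (same shape, strictly positive), `lib_size`, `design`,
#'   `samples`, and `trend` (the lowess curve, for plotting).
#' @export
#' @examples
#' sim <- simulate_expression_counts(sim_config(n_genes = 300, library_size = 1e5))
#' wle <- voom_transform(cpm_filter(sim$counts))
#' range(wle$weights)
voom_transform <- function(x, design = NULL, quantile_normalize = TRUE,
                           span = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  design <- design %||% condition_design(x$samples)
  n <- ncol(counts)
  p <- qr(design)$rank
  if (p < ncol(design)) {
    stop_gsc("design matrix is rank deficient", "gscsoma_design_error")
  }
  if (n <= p) {
    stop_gsc("need more samples than design coefficients", "gscsoma_design_error")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop_gsc("zero library size", "gscsoma_format_error")

  y <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
  if (quantile_normalize) {
    yq <- quantile_normalize(y)
    dimnames(yq) <- dimnames(y)
    y <- yq
  }

  fit <- lm.fit(design, t(y))
  coef <- t(fit$coefficients)                      # genes x p
  res <- t(fit$residuals)
  sigma <- sqrt(rowSums(res^2) / (n - p))
  amean <- rowMeans(y)

  # trend of sqrt(residual sd) vs average log-count
  sx <- amean + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  trend <- lowess(sx, sy, f = span)
  lo <- approxfun(trend, rule = 2, ties = list("ordered", mean))

  fitted_logcpm <- coef %*% t(design)
  fitted_count <- 1e-6 * t(t(2^fitted_logcpm) * (lib + 1))
  w <- matrix(pmax(lo(log2(fitted_count)), 1e-10)^(-4),
              nrow(y), n, dimnames = dimnames(y))

  structure(list(E = y, weights = w, lib_size = lib, design = design,
                 samples = x$samples, trend = trend),
            class = "weighted_logexpr")
}

#' Cell-means design matrix on condition
#'
#' One indicator column per condition (no intercept), named by condition.
#'
#' @param samples A sample sheet tibble with a `condition` column (a
#'   [count_matrix()]'s `$samples` works directly).
#' @return Design matrix with rows in sample order.
#' @export
condition_design <- function(samples) {
  if (inherits(samples, "count_matrix")) samples <- samples$samples
  if (!"condition" %in% names(samples)) {
    samples$condition <- condition_label(samples$genotype, samples$rnai)
  }
  cond <- droplevels(as.factor(samples$condition))
  d <- stats::model.matrix(~ 0 + cond)
  colnames(d) <- levels(cond)
  rownames(d) <- samples$sample
  d
}

#' Contrast vector between two design columns
#'
#' @param design A design matrix with named columns.
#' @param treatment,control Column names; the contrast is
#'   `treatment - control`.
#' @return Numeric contrast vector aligned with the design columns.
#' @export
contrast_vector <- function(design, treatment, control) {
  cn <- colnames(design)
  if (!all(c(treatment, control) %in% cn)) {
    stop_gsc(paste("conditions not in design:", treatment, control),
             "gscsoma_design_error")
  }
  setNames(as.numeric(cn == treatment) - as.numeric(cn == control), cn)
}

#' @export
print.weighted_logexpr <- function(x, ...) {
  cat("<weighted_logexpr>", nrow(x$E), "genes x", ncol(x$E), "samples;",
      "weights in [", format(min(x$weights), digits = 3), ",",
      format(max(x$weights), digits = 3), "]\n")
  invisible(x)
}

#' @export
glance.weighted_logexpr <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$E), n_samples = ncol(x$E),
                 design_rank = qr(x$design)$rank,
                 median_lib_size = median(x$lib_size))
}

#' @describeIn voom_transform Mean-variance trend plot: per-gene
#'   `sqrt(residual sd)` against average log-count with the fitted lowess
#'   curve.
#' @param object,... Method arguments.
#' @export
autoplot.weighted_logexpr <- function(object, ...) {
  fit <- lm.fit(object$design, t(object$E))
  sigma <- sqrt(colSums(fit$residuals^2) / (ncol(object$E) - qr(object$design)$rank))
  pts <- tibble::tibble(
    mean_logcount = rowMeans(object$E) + mean(log2(object$lib_size + 1)) - log2(1e6),
    sqrt_sd = sqrt(sigma)
  )
  trend <- tibble::tibble(x = object$trend$x, y = object$trend$y)
  ggplot2::ggplot(pts, ggplot2::aes(.data$mean_logcount, .data$sqrt_sd)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_line(data = trend, ggplot2::aes(.data$x, .data$y),
                       color = "red", linewidth = 0.8) +
    ggplot2::labs(x = "average log2 count", y = expression(sqrt(sigma)),
                  title = "Mean-variance trend")
}
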