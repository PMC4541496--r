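# Shared fixture builders. Everything is generated in code at test time.

# Minimal weighted_logexpr with unit weights, for driving the model-fitting
# layer with hand-constructed expression values.
make_wle <- function(E, design, weights = NULL) {
  if (is.null(rownames(E))) rownames(E) <- paste0("g", seq_len(nrow(E)))
  if (is.null(colnames(E))) colnames(E) <- paste0("s", seq_len(ncol(E)))
  weights <- weights %||% matrix(1, nrow(E), ncol(E), dimnames = dimnames(E))
  structure(list(E = E, weights = weights,
                 lib_size = rep(1e6, ncol(E)),
                 design = design, samples = NULL, trend = NULL),
            class = "weighted_logexpr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal gene_fit carrying given residual variances/dfs, for exercising the
# moderation layer in isolation.
make_gene_fit <- function(sigma2, df, p = 1) {
  g <- length(sigma2)
  design <- matrix(1, df[1] + p, p)
  colnames(design) <- paste0("b", seq_len(p))
  structure(list(coefficients = matrix(0, g, p),
                 cov_unscaled = array(rep(diag(p), each = g), c(g, p, p)),
                 sigma2 = sigma2, df_residual = rep(df, length.out = g),
                 design = design, genes = paste0("g", seq_len(g))),
            class = "gene_fit")
}

# Independent log-rank statistic (oracle for permutation tests): plain
# observed-minus-expected over shared risk sets, variance by the usual
# hypergeometric formula. Written from the textbook definition, not via
# survival::survdiff.
logrank_chisq_oracle <- function(time, event, group) {
  dt <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group)
    if (n > 1) {
      o_minus_e <- o_minus_e + d1 - d * n1 / n
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (o_minus_e)^2 / v
}

# A small three-condition simulation reused across expression tests.
small_sim <- function(n_genes = 300, seed = 11, ...) {
  simulate_expression_counts(sim_config(n_genes = n_genes, library_size = 2e5,
                                        seed = seed, ...))
}
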