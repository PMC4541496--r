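#' Simulate a three-condition germline-ablation count experiment
#'
#' Draws a gene x sample count matrix for the design WT / germline-ablated
#' (`GSC`) / germline-ablated plus `skn-1` RNAi (`GSC_skn1`), with
#' `n_replicates` biological replicates per condition, together with the
#' generating ground truth.
#'
#' Each gene has a somatic output rate and a germline output rate. Germline
#' rates are scaled so the germline compartment produces exactly
#' `germline_share` of the WT pool. In ablated conditions the germline output
#' is multiplied by `residual_germline`; induced classes get a somatic
#' multiplier of `induction_fc` (and `induction_fc * (1 - knockdown_reduction)`
#' for `skn1_dependent` genes under `skn-1` RNAi). Expected counts are the
#' per-sample renormalized relative abundances times `library_size`, so
#' compositional effects of losing the germline pool propagate to every gene.
#' Counts are negative-binomial around those means.
#'
#' @param config A [sim_config()].
#' @return A list of class `gsc_sim` with elements
#'   \describe{
#'     \item{counts}{a [count_matrix()] (9 samples under the defaults)}
#'     \item{truth}{a tibble: `gene`, `class`, `somatic_rate`,
#'       `germline_rate`, expected relative abundances `pi_WT`, `pi_GSC`,
#'       `pi_GSC_skn1`, and the true fold changes
#'       `true_fc_gsc_vs_wt`, `true_fc_skn1_vs_gsc`}
#'   }
#' @export
#' @examples
#' sim <- simulate_expression_counts(sim_config(n_genes = 200, library_size = 1e5))
#' sim$counts
#' dplyr::count(sim$truth, class)
simulate_expression_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_gsc("`config` must be a sim_config object", "gscsoma_config_error")
  }
  cfg <- config
  classes <- gene_classes(cfg$n_genes, cfg$class_fractions)

  local_seed(cfg$seed, {
    x <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)

    soma <- numeric(cfg$n_genes)
    germ <- numeric(cfg$n_genes)
    soma[classes %in% c("somatic_specific", "gsc_induced", "skn1_dependent")] <-
      x[classes %in% c("somatic_specific", "gsc_induced", "skn1_dependent")]
    germ[classes == "germline_specific"] <- x[classes == "germline_specific"]
    # ubiquitous genes split output like the whole pool (per-nucleus parity)
    ubi <- classes == "ubiquitous"
    soma[ubi] <- (1 - cfg$germline_share) * x[ubi]
    germ[ubi] <- cfg$germline_share * x[ubi]

    # scale the germline-specific rates so the germline makes exactly
    # `germline_share` of the WT pool; ubiquitous genes keep their
    # pool-proportional split so their relative abundance stays flat
    # when the compartment is removed (reference-gene stability)
    if (cfg$germline_share > 0) {
      g <- cfg$germline_share
      need <- g / (1 - g) * sum(soma) - sum(germ[ubi])
      gspec <- classes == "germline_specific"
      if (sum(germ[gspec]) == 0 && need > 1e-9 * sum(soma)) {
        stop_gsc("germline_specific genes are required to reach `germline_share`",
                 "gscsoma_config_error")
      }
      if (any(gspec)) germ[gspec] <- germ[gspec] * need / sum(germ[gspec])
    } else {
      germ <- 0 * germ
    }

    conditions <- c("WT", "GSC", "GSC_skn1")
    germ_mult <- c(WT = 1, GSC = cfg$residual_germline,
                   GSC_skn1 = cfg$residual_germline)
    soma_mult <- matrix(1, cfg$n_genes, 3, dimnames = list(NULL, conditions))
    soma_mult[classes == "gsc_induced", c("GSC", "GSC_skn1")] <- cfg$induction_fc
    soma_mult[classes == "skn1_dependent", "GSC"] <- cfg$induction_fc
    soma_mult[classes == "skn1_dependent", "GSC_skn1"] <-
      cfg$induction_fc * (1 - cfg$knockdown_reduction)

    pool <- vapply(conditions, function(cc) {
      soma * soma_mult[, cc] + germ * germ_mult[[cc]]
    }, numeric(cfg$n_genes))
    pi_mat <- sweep(pool, 2, colSums(pool), "/")

    gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
    sample_ids <- paste0(rep(conditions, each = cfg$n_replicates), "_r",
                         rep(seq_len(cfg$n_replicates), 3))
    mu <- cfg$library_size * pi_mat[, rep(conditions, each = cfg$n_replicates)]
    counts <- matrix(draw_nb(mu, cfg$nb_dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(gene_ids, sample_ids))

    samples <- tibble::tibble(
      sample = sample_ids,
      genotype = rep(c("WT", "GSC-", "GSC-"), each = cfg$n_replicates),
      rnai = rep(c("vector", "vector", "skn-1"), each = cfg$n_replicates),
      replicate = rep(seq_len(cfg$n_replicates), 3)
    )

    truth <- tibble::tibble(
      gene = gene_ids,
      class = classes,
      somatic_rate = soma,
      germline_rate = germ,
      pi_WT = pi_mat[, "WT"],
      pi_GSC = pi_mat[, "GSC"],
      pi_GSC_skn1 = pi_mat[, "GSC_skn1"],
      true_fc_gsc_vs_wt = pi_mat[, "GSC"] / pi_mat[, "WT"],
      true_fc_skn1_vs_gsc = pi_mat[, "GSC_skn1"] / pi_mat[, "GSC"]
    )

    structure(list(counts = count_matrix(counts, samples), truth = truth,
                   config = cfg),
              class = "gsc_sim")
  })
}

# Deterministic class assignment: largest-remainder apportionment of
# n_genes across the five classes, then a fixed ordering.
gene_classes <- function(n_genes, fractions) {
  raw <- n_genes * fractions
  n <- floor(raw)
  rem <- n_genes - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  rep(names(fractions), times = n)
}

# NB draws with variance mu + phi mu^2; phi = 0 degenerates to Poisson.
draw_nb <- function(mu, phi) {
  if (phi == 0) rpois(length(mu), mu) else rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' @export
print.gsc_sim <- function(x, ...) {
  cat("<gsc_sim> seed", x$config$seed, "\n")
  print(x$counts)
  invisible(x)
}
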