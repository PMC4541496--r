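#' Configuration for the expression-count simulator
#'
#' Describes a three-condition bulk RNA-seq experiment on whole animals with
#' two transcript-producing compartments: the soma and the germ line. The
#' wild-type (WT) condition carries both compartments; in the two germline-
#' stem-cell-ablated conditions (`GSC` and `GSC_skn1`) the germline
#' compartment is reduced to a residual fraction of its output. Genes fall
#' into five classes: expressed only in the soma, only in the germ line,
#' ubiquitously (with the per-nucleus split of the whole pool), somatically
#' induced by germline loss, or somatically induced in a manner that depends
#' on the transcription factor SKN-1 (so that `skn-1` RNAi knocks the
#' induction down).
#'
#' Counts are drawn from a negative-binomial distribution with variance
#' `mu + dispersion * mu^2`; a dispersion of zero degenerates to Poisson.
#' Expected counts are renormalized per sample so that the loss of the
#' germline transcript pool propagates compositionally to every gene: a
#' soma-only transcript's expected relative abundance rises by the factor
#' `1 / (1 - germline_share * (1 - residual_germline))` after ablation.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_replicates Biological replicates per condition (at least 2; the
#'   expression filter requires a minimum of two samples).
#' @param library_size Expected total mapped reads per sample.
#' @param germline_share Fraction of the WT transcript pool produced by the
#'   germline compartment, in `[0, 1)`. The default 2/3 mirrors the adult
#'   hermaphrodite's roughly 2:1 ratio of germline to somatic nuclei.
#' @param residual_germline Fraction of germline output remaining after
#'   ablation, in `[0, 1)`. Genetic ablation leaves a very small number of
#'   germline stem cells, hence a small non-zero default.
#' @param class_fractions Named numeric vector of gene-class proportions
#'   (`somatic_specific`, `germline_specific`, `ubiquitous`, `gsc_induced`,
#'   `skn1_dependent`); must sum to 1.
#' @param induction_fc Multiplicative somatic induction applied to
#'   `gsc_induced` and `skn1_dependent` genes in the ablated conditions.
#' @param knockdown_reduction Fractional loss of the `skn1_dependent`
#'   induction under `skn-1` RNAi, in `[0, 1]`: the somatic multiplier in the
#'   `GSC_skn1` condition is `induction_fc * (1 - knockdown_reduction)`.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`); 0 gives Poisson counts.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for per-gene
#'   baseline expression (scale-free; expected counts are renormalized).
#' @param seed Integer random seed; every simulator output is reproducible
#'   from it.
#'
#' @return A `sim_config` object (a validated list).
#' @seealso [simulate_expression_counts()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, library_size = 1e5)
#' cfg$germline_share
sim_config <- function(n_genes = 12595,
                       n_replicates = 3,
                       library_size = 1e7,
                       germline_share = 2 / 3,
                       residual_germline = 0.05,
                       class_fractions = c(somatic_specific = 0.30,
                                           germline_specific = 0.30,
                                           ubiquitous = 0.378,
                                           gsc_induced = 0.015,
                                           skn1_dependent = 0.007),
                       induction_fc = 6,
                       knockdown_reduction = 0.6,
                       nb_dispersion = 0.05,
                       baseline_meanlog = 2,
                       baseline_sdlog = 1.5,
                       seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) {
    stop_gsc("`n_genes` must be a positive count", "gscsoma_config_error")
  }
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    stop_gsc("`n_replicates` must be at least 2 (the expression filter references two samples)",
             "gscsoma_config_error")
  }
  if (!is.numeric(library_size) || library_size <= 0) {
    stop_gsc("`library_size` must be positive", "gscsoma_config_error")
  }
  check_fraction(germline_share, "germline_share")
  check_fraction(residual_germline, "residual_germline")
  check_fraction(knockdown_reduction, "knockdown_reduction", upper_open = FALSE)
  classes <- c("somatic_specific", "germline_specific", "ubiquitous",
               "gsc_induced", "skn1_dependent")
  if (!is.numeric(class_fractions) || !setequal(names(class_fractions), classes)) {
    stop_gsc("`class_fractions` must be a numeric vector named by the five gene classes",
             "gscsoma_config_error")
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8) {
    stop_gsc("`class_fractions` must be non-negative and sum to 1",
             "gscsoma_config_error")
  }
  if (germline_share > 0 &&
      class_fractions[["germline_specific"]] + class_fractions[["ubiquitous"]] == 0) {
    stop_gsc("a positive `germline_share` needs germline-expressed gene classes",
             "gscsoma_config_error")
  }
  if (!is.numeric(induction_fc) || induction_fc <= 0) {
    stop_gsc("`induction_fc` must be positive", "gscsoma_config_error")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    stop_gsc("`nb_dispersion` must be >= 0", "gscsoma_config_error")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         library_size = library_size,
         germline_share = germline_share,
         residual_germline = residual_germline,
         class_fractions = class_fractions,
         induction_fc = induction_fc,
         knockdown_reduction = knockdown_reduction,
         nb_dispersion = nb_dispersion,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "genes x", 3 * x$n_replicates, "samples",
      "(3 conditions x", x$n_replicates, "replicates)\n")
  cat("  germline share:", format(x$germline_share, digits = 3),
      " residual after ablation:", x$residual_germline, "\n")
  cat("  induction fc:", x$induction_fc,
      " skn-1 knockdown reduction:", x$knockdown_reduction,
      " NB dispersion:", x$nb_dispersion, "\n")
  invisible(x)
}

#' Benchmark configuration for screen calibration
#'
#' The randomized-t null behind the dependency screen assumes that a
#' non-dependent gene's t-statistics are null in both contrasts. That holds
#' on a background with no germline compartment and no induced genes; with
#' a real compartment, soma-restricted genes carry a genuine composition
#' fold change in the ablated-vs-WT contrast and the screen must be paired
#' with the fold-change classifiers (see the methods vignette). This
#' constructor builds the matching no-composition benchmark: either a
#' complete null (`n_planted = 0`) or a background with exactly
#' `n_planted` skn-1-dependent genes as the only true effects.
#'
#' @param n_genes Number of genes.
#' @param n_planted Number of skn-1-dependent genes planted (0 for the
#'   global null).
#' @param seed Integer seed.
#' @param ... Further arguments to [sim_config()] (e.g. `induction_fc`,
#'   `knockdown_reduction`, `library_size`).
#' @return A [sim_config()] with `germline_share = 0`, no `gsc_induced`
#'   class, and `class_fractions` set accordingly.
#' @export
screen_benchmark_config <- function(n_genes = 12000, n_planted = 0,
                                    seed = 1L, ...) {
  f_dep <- n_planted / n_genes
  sim_config(
    n_genes = n_genes,
    germline_share = 0,
    residual_germline = 0,
    class_fractions = c(somatic_specific = 0.6,
                        germline_specific = 0,
                        ubiquitous = 0.4 - f_dep,
                        gsc_induced = 0,
                        skn1_dependent = f_dep),
    seed = seed,
    ...
  )
}

# Run code under a local RNG state seeded with `seed`, restoring the global
# state afterwards so simulators never perturb the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
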