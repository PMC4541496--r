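#' Configuration for the survival-cohort simulator
#'
#' @param groups A data frame (or tibble) with one row per group and columns
#'   `genotype`, `rnai`, `mean_lifespan` (days, > 0) and `n` (animals).
#' @param shape Weibull shape parameter shared across groups; larger values
#'   give the tighter, late-life mortality typical of worm lifespan cohorts.
#' @param censor_prob Per-animal probability of being censored (crawling off
#'   the plate, rupture, internal hatching) before death, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `survival_sim_config` object.
#' @export
survival_sim_config <- function(groups, shape = 5, censor_prob = 0.05, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  needed <- c("genotype", "rnai", "mean_lifespan", "n")
  if (!all(needed %in% names(groups))) {
    stop_gsc(paste("`groups` needs columns:", paste(needed, collapse = ", ")),
             "gscsoma_config_error")
  }
  if (any(groups$mean_lifespan <= 0)) {
    stop_gsc("group mean lifespans must be positive", "gscsoma_config_error")
  }
  if (any(groups$n < 1)) {
    stop_gsc("group sizes must be at least 1", "gscsoma_config_error")
  }
  if (shape <= 0) stop_gsc("`shape` must be positive", "gscsoma_config_error")
  check_fraction(censor_prob, "censor_prob")
  structure(list(groups = groups, shape = shape, censor_prob = censor_prob,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a lifespan (or stress-survival) cohort
#'
#' Death times are Weibull with the configured per-group mean; a censored
#' animal is observed only up to a uniform fraction of its death time, with
#' the event flag cleared (it leaves the risk set without a death).
#'
#' @param config A [survival_sim_config()].
#' @return A tibble with one row per animal: `subject`, `time_days`, `event`
#'   (TRUE = death observed), `genotype`, `rnai`, `group`.
#' @export
#' @examples
#' cfg <- survival_sim_config(
#'   tibble::tibble(genotype = c("WT", "GSC-"), rnai = "vector",
#'                  mean_lifespan = c(15.4, 19.9), n = c(50, 50)))
#' simulate_survival_cohort(cfg)
simulate_survival_cohort <- function(config) {
  if (!inherits(config, "survival_sim_config")) {
    stop_gsc("`config` must be a survival_sim_config", "gscsoma_config_error")
  }
  g <- config$groups
  local_seed(config$seed, {
    rows <- purrr::pmap(g, function(genotype, rnai, mean_lifespan, n, ...) {
      scale <- mean_lifespan / gamma(1 + 1 / config$shape)
      death <- rweibull(n, shape = config$shape, scale = scale)
      censored <- runif(n) < config$censor_prob
      time <- ifelse(censored, death * runif(n), death)
      tibble::tibble(time_days = time, event = !censored,
                     genotype = genotype, rnai = rnai)
    })
    out <- dplyr::bind_rows(rows)
    out$subject <- sprintf("animal%04d", seq_len(nrow(out)))
    out$group <- paste(out$genotype, out$rnai, sep = "/")
    dplyr::select(out, "subject", "time_days", "event", "genotype", "rnai", "group")
  })
}

#' Simulate a categorical (high/medium/low) scoring table
#'
#' Multinomial counts per group, emulating scoring of reporter expression
#' into ordered intensity categories.
#'
#' @param probs Named list: one probability vector per group, each summing
#'   to 1 over the categories.
#' @param n Animals scored per group (recycled).
#' @param categories Category labels; defaults to high/medium/low.
#' @param seed Integer seed.
#' @return A tibble with a `group` column and one integer column per category.
#' @export
#' @examples
#' simulate_score_table(list(WT = c(0.1, 0.3, 0.6), `GSC-` = c(0.6, 0.3, 0.1)),
#'                      n = 80, seed = 7)
simulate_score_table <- function(probs, n, categories = c("high", "medium", "low"),
                                 seed = 1L) {
  if (!is.list(probs) || is.null(names(probs))) {
    stop_gsc("`probs` must be a named list of per-group probability vectors",
             "gscsoma_config_error")
  }
  n <- rep_len(n, length(probs))
  for (p in probs) {
    if (length(p) != length(categories) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_gsc("each probability vector must be non-negative, match the categories, and sum to 1",
               "gscsoma_config_error")
    }
  }
  local_seed(seed, {
    counts <- purrr::map2(probs, n, function(p, ni) {
      if (ni == 0) rep(0L, length(p)) else as.integer(rmultinom(1, ni, p))
    })
    out <- tibble::as_tibble(do.call(rbind, counts), .name_repair = "minimal")
    names(out) <- categories
    dplyr::bind_cols(tibble::tibble(group = names(probs)), out)
  })
}
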