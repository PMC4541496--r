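# Published summary tables, transcribed as package data. Each row is one
# cohort's printed summary cell; `pct_ext` is the printed percent extension
# relative to the row named in `control` (NA for control rows). `n_events`
# over `n_total` transcribes the table's "x/y" sample-size column, read as
# observed deaths over animals enrolled.

#' Printed lifespan summary table
#'
#' Mean lifespan, SEM, median, 75th percentile, sample sizes and the printed
#' percent-extension column for the seven lifespan cohorts (composite and
#' replicate experiments at 25 and 20 degrees C, with and without FUdR).
#' These cells are the golden surface for [percent_extension()] and
#' [anova2_from_summary()].
#'
#' @return Tibble with columns `set`, `strain`, `glp1` / `skn1` (factor
#'   levels "wt"/"mut"), `mean`, `sem`, `median`, `p75`, `n_events`,
#'   `n_total`, `pct_ext`, `control`.
#' @export
lifespan_table <- function() {
  r <- function(set, strain, glp1, skn1, mean, sem, med, p75, ev, tot,
                ext = NA_real_, ctrl = NA_character_) {
    tibble::tibble(set = set, strain = strain, glp1 = glp1, skn1 = skn1,
                   mean = mean, sem = sem, median = med, p75 = p75,
                   n_events = ev, n_total = tot, pct_ext = ext,
                   control = ctrl)
  }
  dplyr::bind_rows(
    r("C1", "N2", "wt", "wt", 15.40, 0.2, 16, 17, 133, 148),
    r("C1", "skn-1", "wt", "mut", 14.66, 0.2, 15, 16, 158, 167),
    r("C1", "glp-1", "mut", "wt", 19.94, 0.3, 20, 22, 164, 171, 29.48, "N2"),
    r("C1", "glp-1;skn-1", "mut", "mut", 15.23, 0.2, 15, 18, 149, 170, 3.89, "skn-1"),

    r("#1", "N2", "wt", "wt", 13.99, 0.4, 14, 17, 40, 55),
    r("#1", "skn-1", "wt", "mut", 12.54, 0.3, 13, 14, 41, 50),
    r("#1", "glp-1", "mut", "wt", 22.46, 0.8, 25, 27, 50, 55, 60.54, "N2"),
    r("#1", "glp-1;skn-1", "mut", "mut", 13.29, 0.4, 12, 14, 53, 70, 6.00, "skn-1"),

    r("#2", "N2", "wt", "wt", 16.07, 0.2, 16, 17, 93, 93),
    r("#2", "skn-1", "wt", "mut", 15.42, 0.2, 15, 17, 117, 117),
    r("#2", "glp-1", "mut", "wt", 18.86, 0.3, 19, 21, 114, 116, 17.36, "N2"),
    r("#2", "glp-1;skn-1", "mut", "mut", 16.42, 0.2, 17, 18, 96, 100, 6.49, "skn-1"),

    r("#3", "N2", "wt", "wt", 20.36, 0.6, 18, 21, 42, 50),
    r("#3", "skn-1", "wt", "mut", 18.39, 0.5, 18, 18, 27, 47),
    r("#3", "glp-1", "mut", "wt", 25.87, 1.3, 24, 33, 35, 66, 27.06, "N2"),
    r("#3", "glp-1;skn-1", "mut", "mut", 20.02, 0.6, 18, 24, 34, 55, 8.86, "skn-1"),

    r("C2", "N2", "wt", "wt", 20.51, 0.5, 21, 24, 86, 90),
    r("C2", "skn-1", "wt", "mut", 17.78, 0.4, 19, 20, 88, 94),
    r("C2", "glp-1", "mut", "wt", 24.52, 0.6, 25, 28, 81, 104, 19.55, "N2"),
    r("C2", "glp-1;skn-1", "mut", "mut", 20.47, 0.5, 20, 24, 91, 98, 15.13, "skn-1"),

    r("#4", "N2", "wt", "wt", 18.09, 0.4, 17, 19, 33, 37),
    r("#4", "skn-1", "wt", "mut", 14.78, 0.5, 14, 17, 31, 35),
    r("#4", "glp-1", "mut", "wt", 21.79, 1.0, 21, 28, 28, 50, 20.45, "N2"),
    r("#4", "glp-1;skn-1", "mut", "mut", 16.83, 0.3, 17, 18, 36, 43, 13.87, "skn-1"),

    r("#5", "N2", "wt", "wt", 22.00, 0.6, 23, 25, 53, 53),
    r("#5", "skn-1", "wt", "mut", 19.40, 0.4, 20, 21, 57, 59),
    r("#5", "glp-1", "mut", "wt", 25.91, 0.7, 25, 30, 53, 54, 17.77, "N2"),
    r("#5", "glp-1;skn-1", "mut", "mut", 22.80, 0.6, 24, 26, 55, 55, 17.53, "skn-1")
  )
}

#' Printed stress-resistance summary table
#'
#' Mean survival (hours) under arsenite or tert-butyl hydroperoxide for the
#' ten stress cohorts, with the printed percent-extension column and the
#' control row each extension refers to.
#'
#' @return Tibble with columns `set`, `strain`, `mean`, `sem`, `n_events`,
#'   `n_total`, `pct_ext`, `control`.
#' @export
stress_table <- function() {
  r <- function(set, strain, mean, sem, ev, tot, ext = NA_real_,
                ctrl = NA_character_) {
    tibble::tibble(set = set, strain = strain, mean = mean, sem = sem,
                   n_events = ev, n_total = tot, pct_ext = ext,
                   control = ctrl)
  }
  dplyr::bind_rows(
    r("#1", "N2+vector", 20.20, 1.0, 122, 122),
    r("#1", "N2+rme-2", 39.51, 1.1, 117, 117, 95.59, "N2+vector"),

    r("#2", "N2+vector", 26.82, 1.2, 57, 57),
    r("#2", "N2+rme-2", 53.21, 0.9, 252, 252, 98.44, "N2+vector"),
    r("#2", "glp-1+vector", 53.06, 1.0, 216, 216, 97.85, "N2+vector"),

    r("#3", "N2+vector", 38.59, 0.6, 281, 281),
    r("#3", "N2+rme-2", 63.00, 0.7, 287, 287, 63.25, "N2+vector"),

    r("#4", "N2+vector", 49.10, 0.8, 306, 306),
    r("#4", "N2+vector/skn-1", 32.03, 0.6, 271, 271),
    r("#4", "N2+vector/rme-2", 65.38, 1.1, 361, 361, 33.16, "N2+vector"),
    r("#4", "N2+rme-2/skn-1", 33.76, 0.5, 409, 409, 5.40, "N2+vector/skn-1"),

    r("#5", "N2+vector", 23.18, 0.5, 125, 125),
    r("#5", "N2+lipl-3", 23.04, 0.6, 139, 139),
    r("#5", "N2+sbp-1", 11.01, 0.6, 163, 163),
    r("#5", "N2+skn-1", 20.88, 0.7, 115, 115),
    r("#5", "glp-1+vector", 40.58, 1.1, 105, 105, 75.05, "N2+vector"),
    r("#5", "glp-1+lipl-3", 28.52, 1.0, 178, 178, 23.77, "N2+lipl-3"),
    r("#5", "glp-1+sbp-1", 7.50, 0.5, 138, 138, -31.88, "N2+sbp-1"),
    r("#5", "glp-1+skn-1", 12.90, 0.9, 129, 129, -38.21, "N2+skn-1"),

    r("#6", "N2+vector", 24.36, 0.8, 121, 121),
    r("#6", "N2+fat-6/7", 15.56, 0.8, 159, 159),
    r("#6", "N2+skn-1", 20.94, 0.6, 124, 124),
    r("#6", "glp-1+vector", 38.49, 1.5, 98, 98, 58.03, "N2+vector"),
    r("#6", "glp-1+fat-6/7", 12.04, 0.7, 153, 153, -22.66, "N2+fat-6/7"),
    r("#6", "glp-1+skn-1", 23.69, 0.9, 116, 116, 13.13, "N2+skn-1"),

    r("#7", "N2+vector", 6.55, 0.3, 104, 104),
    r("#7", "N2+skn-1", 5.08, 0.2, 103, 103),
    r("#7", "glp-1+vector", 19.36, 0.1, 97, 97, 195.57, "N2+vector"),
    r("#7", "glp-1+skn-1", 7.86, 0.4, 100, 100, 54.72, "N2+skn-1"),

    r("#8", "N2+vector", 8.31, 0.4, 98, 98),
    r("#8", "N2+skn-1", 6.89, 0.3, 90, 90),
    r("#8", "glp-1+vector", 16.95, 1.0, 81, 81, 103.97, "N2+vector"),
    r("#8", "glp-1+skn-1", 9.90, 0.4, 91, 91, 43.69, "N2+skn-1"),

    r("#9", "N2+vector", 9.02, 0.3, 84, 108),
    r("#9", "N2+skn-1", 6.16, 0.2, 63, 98),
    r("#9", "glp-1+vector", 11.62, 0.3, 61, 61, 28.82, "N2+vector"),
    r("#9", "glp-1+skn-1", 6.48, 0.1, 63, 65, 5.19, "N2+skn-1"),

    r("#10", "N2", 4.29, 0.2, 65, 94),
    r("#10", "skn-1", 4.51, 0.1, 73, 74),
    r("#10", "glp-1", 6.25, 0.2, 73, 74, 45.69, "N2"),
    r("#10", "glp-1;skn-1", 4.78, 0.1, 73, 75, 5.99, "skn-1")
  )
}

#' Published RNA-seq gene tallies and nuclei counts
#'
#' The headline counts of the expression study: genes passing the
#' expression filter, genes above the fourfold and fivefold cutoffs, the
#' SKN-1-dependent fourfold set, and the somatic/germline nuclei counts
#' behind the composition model.
#'
#' @return One-row tibble.
#' @export
study_gene_counts <- function() {
  tibble::tibble(n_expressed = 12595L,
                 n_fc_gt4 = 1306L,
                 n_fc_gt5 = 615L,
                 n_skn1_dependent_fc4 = 87L,
                 n_soma_nuclei = 959L,
                 n_germ_nuclei = 2000L)
}

#' Recompute a summary table's percent-extension column
#'
#' Joins each treated row to its control row and recomputes the percent
#' extension from the printed means with [percent_extension()], alongside
#' the printed value and the tolerance implied by the table's printed
#' precision (means rounded to 0.01 propagate to roughly 0.05-0.1
#' percentage points).
#'
#' @param table A tibble shaped like [lifespan_table()] or
#'   [stress_table()].
#' @return Tibble of the treated rows: `set`, `strain`, `computed_ext`,
#'   `printed_ext`, `printed_tolerance`.
#' @export
#' @examples
#' recompute_extensions(lifespan_table())
recompute_extensions <- function(table) {
  treated <- dplyr::filter(table, !is.na(.data$pct_ext))
  ctrl_mean <- purrr::map2_dbl(treated$set, treated$control, function(s, ctrl) {
    row <- dplyr::filter(table, .data$set == s, .data$strain == ctrl)
    if (nrow(row) != 1) {
      stop_gsc(paste("control row not found:", s, ctrl), "gscsoma_format_error")
    }
    row$mean
  })
  half_unit <- 0.005  # printed means carry 2 decimals
  tibble::tibble(
    set = treated$set,
    strain = treated$strain,
    computed_ext = percent_extension(treated$mean, ctrl_mean),
    printed_ext = treated$pct_ext,
    printed_tolerance = 100 * (half_unit / ctrl_mean +
                                 treated$mean * half_unit / ctrl_mean^2) +
      half_unit
  )
}
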