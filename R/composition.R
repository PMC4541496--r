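#' Two-compartment nuclei composition model
#'
#' Encodes the composition argument behind the fold-change cutoff: the adult
#' hermaphrodite soma has 959 nuclei while the germ line contributes roughly
#' 2000, so removing the germline transcript pool raises the relative
#' abundance of every soma-restricted transcript even without any regulation.
#'
#' @param n_soma Somatic nuclei count (default 959).
#' @param n_germ Germline nuclei count (default 2000).
#' @param rho Per-nucleus transcript output of germline relative to soma
#'   (default 1: output proportional to nuclei).
#' @param residual_germline Fraction of germline output remaining after
#'   ablation.
#' @return A `composition_model` object.
#' @export
#' @examples
#' expected_enrichment(composition_model())            # 2959/959 = 3.086
#' expected_enrichment(composition_model(n_soma = 1, n_germ = 2))  # 3
composition_model <- function(n_soma = 959, n_germ = 2000, rho = 1,
                              residual_germline = 0) {
  if (n_soma <= 0 || n_germ <= 0) {
    stop_gsc("nuclei counts must be positive", "gscsoma_config_error")
  }
  if (rho < 0) stop_gsc("`rho` must be >= 0", "gscsoma_config_error")
  check_fraction(residual_germline, "residual_germline")
  structure(list(n_soma = n_soma, n_germ = n_germ, rho = rho,
                 residual_germline = residual_germline),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat("<composition_model>", x$n_soma, "somatic /", x$n_germ,
      "germline nuclei; rho =", x$rho, "; residual =", x$residual_germline, "\n")
  cat("  predicted soma-transcript enrichment:",
      format(expected_enrichment(x), digits = 4), "\n")
  invisible(x)
}

#' Predicted enrichment of a soma-only transcript after germline loss
#'
#' The transcript's absolute output is unchanged, but the pool shrinks from
#' `n_soma + rho*n_germ` to `n_soma + rho*n_germ*residual`, so its relative
#' abundance rises by the ratio of the two. With no residual germ line and
#' a 2:1 germline-to-soma nuclei ratio this predicts a threefold enrichment.
#'
#' @param model A [composition_model()].
#' @return Scalar enrichment factor (>= 1).
#' @export
expected_enrichment <- function(model) {
  stopifnot(inherits(model, "composition_model"))
  germ_out <- model$rho * model$n_germ
  (model$n_soma + germ_out) /
    (model$n_soma + germ_out * model$residual_germline)
}

#' Marker panel of tissue-restricted and reference genes
#'
#' @param somatic,germline,reference Disjoint, non-empty character vectors
#'   of gene ids: soma-specific markers, germline-specific markers, and
#'   ubiquitously expressed reference (housekeeping) genes.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(somatic, germline, reference) {
  lists <- list(somatic = somatic, germline = germline, reference = reference)
  if (any(lengths(lists) == 0)) {
    stop_gsc("all three marker lists must be non-empty", "gscsoma_config_error")
  }
  all_ids <- unlist(lists)
  if (anyDuplicated(all_ids)) {
    stop_gsc("marker lists must be disjoint", "gscsoma_config_error")
  }
  structure(lists, class = "marker_panel")
}

#' Read a marker panel from a sectioned plain-text file
#'
#' Sections are introduced by lines `[somatic]`, `[germline]`,
#' `[reference]`; one gene id per line elsewhere.
#'
#' @param path File path.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  section <- cumsum(grepl("^\\[.*\\]$", lines))
  names_at <- gsub("\\[|\\]", "", lines[grepl("^\\[.*\\]$", lines)])
  ids <- split(lines[!grepl("^\\[.*\\]$", lines)],
               names_at[section[!grepl("^\\[.*\\]$", lines)]])
  marker_panel(somatic = ids$somatic, germline = ids$germline,
               reference = ids$reference)
}

#' Calibrate observed fold changes against a marker panel
#'
#' Summarizes the ablated-vs-WT fold-change distribution within each marker
#' class and checks the composition model's qualitative predictions: the
#' reference genes should be stable (median FC within `1 +/- tolerance`)
#' and the germline markers depleted (median FC < 1). The somatic-marker
#' median is the data-driven estimate of the composition enrichment.
#'
#' @param fc_table Tibble with columns `gene` and `fc` (linear-scale fold
#'   change, ablated vs WT).
#' @param panel A [marker_panel()]; every panel gene must be in `fc_table`.
#' @param tolerance Stability band half-width for reference genes.
#' @return A `marker_calibration` object; `tidy()` gives the per-class
#'   summary, `glance()` the flags and the enrichment estimate.
#' @export
calibrate_markers <- function(fc_table, panel, tolerance = 0.2) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!all(c("gene", "fc") %in% names(fc_table))) {
    stop_gsc("`fc_table` needs columns gene and fc", "gscsoma_format_error")
  }
  missing <- setdiff(unlist(panel), fc_table$gene)
  if (length(missing)) {
    stop_gsc(paste("panel genes missing from fc_table:",
                   paste(missing, collapse = ", ")),
             "gscsoma_format_error")
  }
  summary <- purrr::imap_dfr(unclass(panel), function(ids, cls) {
    fc <- fc_table$fc[match(ids, fc_table$gene)]
    tibble::tibble(class = cls, n = length(fc),
                   median_fc = median(fc),
                   q25 = quantile(fc, 0.25, names = FALSE),
                   q75 = quantile(fc, 0.75, names = FALSE))
  })
  med <- setNames(summary$median_fc, summary$class)
  structure(list(summary = summary,
                 reference_stable = abs(med[["reference"]] - 1) <= tolerance,
                 germline_depleted = med[["germline"]] < 1,
                 somatic_enrichment = med[["somatic"]],
                 tolerance = tolerance),
            class = "marker_calibration")
}

#' @export
print.marker_calibration <- function(x, ...) {
  cat("<marker_calibration> somatic-marker enrichment:",
      format(x$somatic_enrichment, digits = 4), "\n")
  cat("  reference stable:", x$reference_stable,
      " germline depleted:", x$germline_depleted, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.marker_calibration <- function(x, ...) x$summary

#' @export
glance.marker_calibration <- function(x, ...) {
  tibble::tibble(somatic_enrichment = x$somatic_enrichment,
                 reference_stable = x$reference_stable,
                 germline_depleted = x$germline_depleted,
                 tolerance = x$tolerance)
}

#' Write a calibration report as JSON
#'
#' @param x A `marker_calibration`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_calibration_report <- function(x, path) {
  stopifnot(inherits(x, "marker_calibration"))
  jsonlite::write_json(
    list(summary = x$summary,
         flags = list(reference_stable = x$reference_stable,
                      germline_depleted = x$germline_depleted),
         somatic_enrichment = x$somatic_enrichment),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Call genes upregulated in the soma after germline loss
#'
#' A gene not on the somatic-specific panel is called when its
#' ablated-vs-WT fold change exceeds the cutoff
#' `max(4, expected_enrichment(model) * margin)`: the composition model sets
#' the floor that mere compartment loss can produce, the margin adds
#' headroom above it, and the published fourfold threshold is never
#' undercut. With the default nuclei counts and `margin = 1`, the cutoff is
#' exactly 4.
#'
#' @param fc_table Tibble with columns `gene`, `fc`.
#' @param model A [composition_model()].
#' @param margin Multiplier (>= 1) on the predicted enrichment.
#' @param panel Optional [marker_panel()]; its somatic-specific genes are
#'   excluded from calling (they rise for compositional reasons alone).
#' @return Tibble of called genes (`gene`, `fc`) with the cutoff and the
#'   model prediction attached as attributes.
#' @export
call_somatic_upregulated <- function(fc_table, model = composition_model(),
                                     margin = 1, panel = NULL) {
  if (margin < 1) stop_gsc("`margin` must be >= 1", "gscsoma_config_error")
  e <- expected_enrichment(model)
  cutoff <- max(4, e * margin)
  candidates <- fc_table
  if (!is.null(panel)) {
    candidates <- dplyr::filter(candidates, !.data$gene %in% panel$somatic)
  }
  out <- dplyr::filter(candidates, .data$fc > cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "predicted_enrichment") <- e
  out
}
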