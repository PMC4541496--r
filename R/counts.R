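#' Gene-by-sample count container
#'
#' A light wrapper holding an integer gene x sample count matrix together
#' with a sample sheet (one row per sample: id, genotype, RNAi treatment,
#' replicate). This is the unit every expression function consumes.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples A data frame with columns `sample`, `genotype`, `rnai`,
#'   `replicate`; one row per column of `counts`, in any order.
#'
#' @return A `count_matrix` object.
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- tibble::tibble(sample = colnames(m),
#'                         genotype = c("WT", "WT", "GSC-", "GSC-"),
#'                         rnai = "vector", replicate = c(1, 2, 1, 2))
#' count_matrix(m, sheet)
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_gsc("`counts` must be a matrix with gene rownames and sample colnames",
             "gscsoma_format_error")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_gsc("counts must be non-negative integers with no missing values",
             "gscsoma_format_error")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_gsc("duplicate gene ids in count matrix", "gscsoma_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_gsc("duplicate sample ids in count matrix", "gscsoma_format_error")
  }
  samples <- tibble::as_tibble(samples)
  needed <- c("sample", "genotype", "rnai", "replicate")
  if (!all(needed %in% names(samples))) {
    stop_gsc(paste("sample sheet must have columns:", paste(needed, collapse = ", ")),
             "gscsoma_metadata_error")
  }
  if (!setequal(samples$sample, colnames(counts)) ||
      nrow(samples) != ncol(counts)) {
    missing <- setdiff(colnames(counts), samples$sample)
    extra <- setdiff(samples$sample, colnames(counts))
    stop_gsc(paste0("sample sheet does not match count matrix columns",
                    if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
                    if (length(extra)) paste0("; unmatched: ", paste(extra, collapse = ", "))),
             "gscsoma_metadata_error")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  samples$condition <- condition_label(samples$genotype, samples$rnai)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

# Map (genotype, rnai) to the condition labels used in designs/contrasts.
condition_label <- function(genotype, rnai) {
  lab <- dplyr::case_when(
    genotype == "WT" & rnai == "vector" ~ "WT",
    genotype == "GSC-" & rnai == "vector" ~ "GSC",
    genotype == "GSC-" & rnai == "skn-1" ~ "GSC_skn1",
    TRUE ~ paste(genotype, rnai, sep = ".")
  )
  factor(lab, levels = unique(c("WT", "GSC", "GSC_skn1", lab)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(dplyr::count(x$samples, .data$condition))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts per million mapped reads
#'
#' @param x A `count_matrix` or a bare counts matrix.
#' @param lib_size Optional library sizes; defaults to column sums.
#' @return Numeric matrix of CPM values, same shape as the counts.
#' @export
cpm <- function(x, lib_size = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  lib_size <- lib_size %||% colSums(m)
  if (any(lib_size <= 0)) {
    stop_gsc("every library sum must be positive to compute CPM",
             "gscsoma_format_error")
  }
  sweep(m, 2, lib_size, "/") * 1e6
}

#' Read a count matrix and sample sheet from disk
#'
#' Expects a tab-separated counts file in the style of featureCounts output
#' reduced to its matrix part: a gene-identifier first column and one integer
#' column per sample, with a header row of sample ids. The sample sheet is a
#' CSV with columns `sample`, `genotype`, `rnai`, `replicate`.
#'
#' @param counts_path Path to the TSV count matrix.
#' @param sample_sheet_path Path to the CSV sample sheet.
#' @return A validated [count_matrix()].
#' @export
load_counts <- function(counts_path, sample_sheet_path) {
  for (p in c(counts_path, sample_sheet_path)) {
    if (!file.exists(p)) stop_gsc(paste("file not found:", p), "gscsoma_format_error")
  }
  tab <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (ncol(tab) < 2) {
    stop_gsc("counts file needs a gene column plus at least one sample column",
             "gscsoma_format_error")
  }
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[-1])
  if (!is.numeric(m)) {
    stop_gsc("sample columns must be numeric counts", "gscsoma_format_error")
  }
  rownames(m) <- genes
  sheet <- readr::read_csv(sample_sheet_path, show_col_types = FALSE)
  cm <- count_matrix(m, sheet)
  message(sprintf("loaded %d genes x %d samples from %s",
                  nrow(cm$counts), ncol(cm$counts), counts_path))
  cm
}

#' Write a count matrix (and optional ground truth) to disk
#'
#' Emits `counts.tsv` (gene column + one column per sample), `samples.csv`,
#' and, when a simulation truth table is supplied, `truth.tsv`.
#'
#' @param x A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @param truth Optional gene-truth tibble from the simulator.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(x, dir, truth = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(gene = rownames(x$counts)),
                     tibble::as_tibble(x$counts)),
    counts_path
  )
  samples_path <- file.path(dir, "samples.csv")
  readr::write_csv(dplyr::select(x$samples, -"condition"), samples_path)
  paths <- c(counts_path, samples_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}
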