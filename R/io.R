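# Readers and writers: dense delimited expression matrices, sparse
# matrix-market triplets with row/column identifier files, DEG tables,
# ledgers, ground truth and pipeline configuration.

#' Read an expression matrix
#'
#' Dense format: tab-delimited with a header row and gene identifiers in the
#' first column. Triplet format: matrix-market file plus one-identifier-per-
#' line row and column files. Duplicate gene identifiers are collapsed by
#' keeping the row with the largest total count (a warning reports how many).
#'
#' @param path dense matrix path, or matrix-market path for `format = "mtx"`.
#' @param format `"dense"` or `"mtx"`.
#' @param row_path,col_path identifier files (triplet format only).
#' @return genes x samples matrix (dense) or `dgCMatrix` (mtx).
#' @export
read_expression <- function(path, format = c("dense", "mtx"),
                            row_path = NULL, col_path = NULL) {
  format <- match.arg(format)
  check(file.exists(path), sprintf("file not found: %s", path))
  if (format == "dense") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    check(ncol(df) >= 2L, "dense matrix needs a gene column plus >= 1 sample")
    genes <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
    mat <- collapse_duplicate_genes(mat)
    return(mat)
  }
  check(!is.null(row_path) && !is.null(col_path),
        "triplet format needs row_path and col_path")
  m <- Matrix::readMM(path)
  rows <- readLines(row_path, warn = FALSE)
  cols <- readLines(col_path, warn = FALSE)
  check(length(rows) == nrow(m) && length(cols) == ncol(m),
        sprintf("dimension mismatch: matrix %dx%d vs %d row ids and %d column ids",
                nrow(m), ncol(m), length(rows), length(cols)))
  dimnames(m) <- list(rows, cols)
  methods::as(m, "CsparseMatrix")
}

collapse_duplicate_genes <- function(mat) {
  dup <- duplicated(rownames(mat)) | duplicated(rownames(mat), fromLast = TRUE)
  if (!any(dup)) return(mat)
  totals <- rowSums(mat)
  ord <- order(rownames(mat), -totals)
  mat <- mat[ord, , drop = FALSE]
  keep <- !duplicated(rownames(mat))
  warning(sprintf("collapsed %d duplicate gene row(s), keeping the largest total",
                  sum(!keep)), call. = FALSE)
  mat[keep, , drop = FALSE]
}

#' Write an expression matrix as delimited text
#'
#' @param mat genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  check_matrix(mat)
  df <- data.frame(gene = rownames(mat), as.matrix(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sparse matrix as matrix-market triplets
#'
#' Writes `<stem>.mtx`, `<stem>.rows` and `<stem>.cols`.
#'
#' @param mat sparse (or dense) matrix with dimnames.
#' @param stem output path stem.
#' @return character vector of the three paths, invisibly.
#' @export
write_mtx <- function(mat, stem) {
  check_matrix(mat)
  m <- Matrix::Matrix(as.matrix(mat), sparse = TRUE)
  paths <- paste0(stem, c(".mtx", ".rows", ".cols"))
  Matrix::writeMM(m, paths[[1]])
  writeLines(rownames(mat), paths[[2]])
  writeLines(colnames(mat), paths[[3]])
  invisible(paths)
}

#' Pipeline configuration
#'
#' All knobs of [run_pipeline()]: synthetic-data parameters, filtering and
#' scoring thresholds, stage toggles and the master seed. Unknown keys are
#' rejected, which catches config-file typos.
#'
#' @param ... overrides of the defaults listed below.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_genes = 2000L,
    cell_types = c("NK", "T", "B", "Monocyte", "Neutrophil", "DC", "Myeloid"),
    n_replicates = 4L,
    n_markers = 30L, n_leaky = 5L, n_stromal = 5L,
    marker_fold = 8, dispersion = 0.1, dropout_rate = 0.3,
    n_cells_per_type = 60L,
    n_lines = 20L, n_patients = 6L,
    min_cpm = 1, min_samples = 4L, pseudo = 0.5,
    lfc_cut = 1, alpha = 0.05,
    filter_median = TRUE, filter_tumour = TRUE, filter_stromal = TRUE,
    filter_sc = TRUE, stromal_significance = TRUE,
    ratio_cut = 2, frac_cut = 0.25, k = 2L,
    n_mixtures = 100L, mixture_fraction_max = 0.2, q = 0.10,
    survival_log_hr = -0.7, censoring_rate = 0.2, survival_n = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  check(length(unknown) == 0L,
        sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, overrides)
  check(cfg$q > 0 && cfg$q < 0.5, "q must lie in (0, 0.5)")
  check(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  check(cfg$mixture_fraction_max > 0 && cfg$mixture_fraction_max <= 1,
        "mixture_fraction_max must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   unknown keys raise an error.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  check(file.exists(path), sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  check(is.list(vals), "config file must contain a YAML mapping")
  do.call(pipeline_config, vals)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_table_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
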