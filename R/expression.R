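#' Read a normalized expression matrix
#'
#' Reads a genes x cells normalized (typically log-normalized) expression
#' matrix from either a Matrix Market triplet (`.mtx` plus gene and barcode
#' sidecar files, 10x convention: genes are MTX rows) or a dense delimited
#' table with gene identifiers in the first column and cell identifiers in the
#' header. The returned matrix is always genes x cells; set
#' `genes_as_rows = FALSE` when the on-disk orientation is transposed.
#'
#' @param counts_path Path to the `.mtx` file or the dense table.
#' @param genes_path,cells_path Sidecar files with one identifier per line
#'   (first column used if multi-column). Required for the MTX dialect.
#' @param dialect One of `"mtx_triplet"`, `"dense_table"`, `"h5_container"`.
#'   The HDF5 dialect requires an HDF5 binding and is not available in this
#'   build; it raises an informative error.
#' @param genes_as_rows Logical; whether on-disk rows are genes (default TRUE).
#' @param sep Field separator for the dense dialect (default tab).
#'
#' @return A sparse `dgCMatrix` (genes x cells) with gene/cell dimnames.
#' @export
read_expression <- function(counts_path,
                            genes_path = NULL,
                            cells_path = NULL,
                            dialect = c("mtx_triplet", "dense_table", "h5_container"),
                            genes_as_rows = TRUE,
                            sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(counts_path)) {
    stop_locat(sprintf("counts file not found: %s", counts_path), "locat_io_error")
  }
  if (dialect == "h5_container") {
    stop_locat("the HDF5 container dialect requires an HDF5 R binding; export the matrix as an MTX triplet or dense table instead",
               "locat_format_error")
  }
  if (dialect == "mtx_triplet") {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop_locat("mtx_triplet dialect needs genes_path and cells_path sidecars",
                 "locat_format_error")
    }
    m <- Matrix::readMM(counts_path)
    genes <- read_id_column(genes_path)
    cells <- read_id_column(cells_path)
    if (!genes_as_rows) m <- Matrix::t(m)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop_locat(sprintf(
        "sidecar/matrix dimension mismatch: %d gene ids vs %d rows, %d cell ids vs %d columns",
        length(genes), nrow(m), length(cells), ncol(m)), "locat_format_error")
    }
    dimnames(m) <- list(genes, cells)
    return(as_expression_matrix(m))
  }
  # dense table
  tab <- utils::read.delim(counts_path, sep = sep, header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!genes_as_rows) m <- t(m)
  as_expression_matrix(m)
}

read_id_column <- function(path) {
  if (!file.exists(path)) {
    stop_locat(sprintf("sidecar file not found: %s", path), "locat_io_error")
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  tab[[1L]]
}

#' Gene prevalences
#'
#' Fraction of cells with nonzero expression, per gene.
#'
#' @param expr Genes x cells matrix (sparse or dense).
#' @return Named numeric vector of prevalences in `[0, 1]`.
#' @export
gene_prevalence <- function(expr) {
  expr <- as_expression_matrix(expr)
  Matrix::rowSums(expr > 0) / ncol(expr)
}

#' Default gene-symbol exclusion patterns
#'
#' Regular expressions matching symbols of predicted, uncharacterized or
#' non-protein-coding loci in mouse-style nomenclature: `Gm`-prefixed models,
#' `Rik` clone identifiers, and `AC`/`AA` BAC-derived names. Matching is
#' case-insensitive (prefix conventions differ across species).
#'
#' @return Character vector of regular expressions.
#' @export
default_exclusion_patterns <- function() {
  c("^Gm\\d", "Rik$", "^AC\\d", "^AA\\d")
}

#' Filter genes by prevalence and symbol rules
#'
#' Retains genes expressed in at least `min_prevalence` of cells whose symbols
#' match none of the exclusion patterns. Gene order is preserved and the
#' operation is idempotent.
#'
#' @param expr Genes x cells expression matrix.
#' @param min_prevalence Minimum fraction of expressing cells, in `[0, 1)`.
#' @param exclude_patterns Character vector of regular expressions applied
#'   case-insensitively to gene identifiers; matching genes are dropped. Use
#'   `character(0)` to disable.
#'
#' @return The filtered sparse matrix.
#' @export
preprocess_genes <- function(expr,
                             min_prevalence = 0.01,
                             exclude_patterns = default_exclusion_patterns()) {
  expr <- as_expression_matrix(expr)
  if (!is_scalar_number(min_prevalence) || min_prevalence < 0 || min_prevalence >= 1) {
    stop_locat("min_prevalence must be a single value in [0, 1)", "locat_validation_error")
  }
  keep <- gene_prevalence(expr) >= min_prevalence
  if (length(exclude_patterns)) {
    excluded <- Reduce(`|`, lapply(exclude_patterns, function(p) {
      grepl(p, rownames(expr), ignore.case = TRUE)
    }))
    keep <- keep & !excluded
  }
  if (!any(keep)) {
    stop_locat("no genes survive filtering; lower min_prevalence or relax exclusion patterns",
               "locat_empty_result_error")
  }
  expr[keep, , drop = FALSE]
}

result_columns <- c("gene_id", "p_tilde", "p_loc", "p_conc", "p_depl",
                    "z_conc", "k_components", "bic_like", "n_expr", "prevalence")

#' Write per-gene localization results
#'
#' Writes a tab-separated table with one row per gene, sorted by the final
#' localization p-value ascending (gene identifier breaks ties). Floats are
#' written at full precision so a read-back reproduces them exactly.
#'
#' @param results Tibble of per-gene results (as returned by [locat()] or
#'   [tidy.locat()]).
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
write_locat_results <- function(results, out_path) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) {
    stop_locat("results table is empty", "locat_validation_error")
  }
  missing <- setdiff(result_columns, names(results))
  if (length(missing)) {
    stop_locat(paste0("results table lacks columns: ", paste(missing, collapse = ", ")),
               "locat_validation_error")
  }
  results <- dplyr::arrange(results[result_columns], .data$p_tilde, .data$gene_id)
  out <- results
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.table(out, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_locat(sprintf("cannot write results to %s", out_path), "locat_io_error")
  invisible(out_path)
}

#' Read back a localization results table
#'
#' @param path Path written by [write_locat_results()].
#' @return Tibble of per-gene results.
#' @export
read_locat_results <- function(path) {
  if (!file.exists(path)) stop_locat(sprintf("file not found: %s", path), "locat_io_error")
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = c(gene_id = "character"))
  as_tibble(tab)
}
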