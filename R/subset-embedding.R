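#' Embedding from a gene subset
#'
#' Principal components of the expression matrix restricted to a gene subset
#' (cells x `n_pcs` scores; centered, unscaled PCA). Used to build embeddings
#' from, for example, the union of localized genes across conditions. The
#' sign of each component is fixed so that its largest-magnitude gene loading
#' is positive, making the output deterministic.
#'
#' @param expr Genes x cells expression matrix.
#' @param gene_subset Gene identifiers to keep (must exist in the matrix).
#' @param n_pcs Number of components (at most `min(subset size, n cells)`).
#' @return A cells x `n_pcs` matrix with cell identifiers as row names.
#' @export
subset_embedding <- function(expr, gene_subset = rownames(expr), n_pcs = 8L) {
  expr <- as_expression_matrix(expr)
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing)) {
    stop_locat(paste0("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", ")),
               "locat_lookup_error")
  }
  if (length(gene_subset) < n_pcs) {
    stop_locat("gene subset smaller than the requested number of components",
               "locat_validation_error")
  }
  x <- t(as.matrix(expr[gene_subset, , drop = FALSE])) # cells x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2L, flip, `*`)
  rownames(scores) <- colnames(expr)
  scores
}
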