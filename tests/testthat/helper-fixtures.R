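# Shared fixture builders. Everything is generated in code; no stored data.

# Tiny named sparse expression matrix from a dense numeric matrix.
make_expr <- function(m, genes = NULL, cells = NULL) {
  m <- as.matrix(m)
  genes <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% colnames(m) %||% sprintf("c%02d", seq_len(ncol(m)))
  out <- Matrix::Matrix(m, sparse = TRUE)
  dimnames(out) <- list(genes, cells)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a 10x-style MTX triplet into a temp dir; returns the three paths.
write_mtx_triplet <- function(m, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE), mtx)
  genes <- file.path(dir, "genes.tsv")
  cells <- file.path(dir, "barcodes.tsv")
  writeLines(rownames(m), genes)
  writeLines(colnames(m), cells)
  list(mtx = mtx, genes = genes, cells = cells)
}

# A small localization run fixture: embedding + one planted + null genes.
small_run <- function(n_cells = 400, n_null = 3, seed = 5, radius = 0.25,
                      n_expressing = 60) {
  simulate_dataset(n_cells = n_cells, d = 2, n_localized = 1, n_null = n_null,
                   radius = radius, n_expressing = n_expressing, seed = seed)
}

fast_control <- function(seed = 0L) {
  benchmark_control(seed = seed)
}
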