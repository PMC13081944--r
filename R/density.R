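# Background and gene-specific density estimation on the embedding.

#' Fit the background cell density
#'
#' Fits a weighted Gaussian mixture to all cells in the embedding (uniform
#' per-cell weights by default), selecting the component count by the
#' effective-sample-size BIC over `k_grid`, then averages the per-cell density
#' over `n_inits` refits at the selected count with distinct initialisation
#' seeds. Averaging stabilises the background density values that every
#' downstream contrast depends on.
#'
#' @param emb Cells x d embedding matrix.
#' @param cell_weights Optional nonnegative per-cell weights (for example
#'   total counts); uniform if `NULL`.
#' @param k_grid Candidate component counts.
#' @param n_inits Number of refits averaged at the selected count.
#' @param seed Master seed.
#' @param reg Covariance ridge passed to [fit_wgmm()].
#' @param floor Density floor (keeps ratios finite).
#'
#' @return An object of class `"background_density"` with `per_cell_density`,
#'   `fitted_models` (list of `"wgmm"`), `k0`, `bic_grid`.
#' @export
fit_background <- function(emb, cell_weights = NULL, k_grid = 1:10,
                           n_inits = 5L, seed = 0L, reg = NULL, floor = 1e-300) {
  emb <- check_embedding(emb)
  if (!length(k_grid)) stop_locat("k_grid must be nonempty", "locat_validation_error")
  n <- nrow(emb)
  if (is.null(cell_weights)) cell_weights <- rep(1, n)
  bic_grid <- vapply(k_grid, function(k) {
    m <- fit_wgmm(emb, cell_weights, k = k, seed = sub_seed(seed, 17L, k), reg = reg)
    wgmm_bic(m, emb, cell_weights)
  }, numeric(1))
  k0 <- k_grid[which.min(bic_grid)]
  models <- lapply(seq_len(n_inits), function(i) {
    fit_wgmm(emb, cell_weights, k = k0, seed = sub_seed(seed, 29L, i), reg = reg)
  })
  dens <- vapply(models, wgmm_density, numeric(n), points = emb, floor = floor)
  per_cell <- pmax(rowMeans(matrix(dens, nrow = n)), floor)
  structure(list(
    per_cell_density = per_cell,
    fitted_models = models,
    k0 = as.integer(k0),
    bic_grid = stats::setNames(bic_grid, k_grid)
  ), class = "background_density")
}

# Support-adaptive upper bound on the component count for a gene model:
# one component per ~20 effective observations, at least 1, capped.
gene_k_max <- function(weights, k_max_cap = 10L) {
  neff <- kish_neff(weights)
  max(1L, min(as.integer(floor(neff / 20)), as.integer(k_max_cap), 10L))
}

#' Fit a gene-specific expression density
#'
#' Fits weighted Gaussian mixtures to the embedding using the gene's
#' normalized expression values as observation weights, selecting the
#' component count `K_g` by the effective-sample-size BIC over
#' `1..k_max(g)`. The upper bound adapts to support: genes spread across
#' larger effective samples may use more components, compact or sparse genes
#' fewer (one component per ~20 effective observations, capped at
#' `k_max_cap`).
#'
#' @param emb Cells x d embedding.
#' @param gene_weights Nonnegative expression weights of length `nrow(emb)`;
#'   at least one must be positive.
#' @param k_max_cap Hard cap on the component count.
#' @param seed Integer seed.
#' @param reg Covariance ridge passed to [fit_wgmm()].
#'
#' @return A `"wgmm"` object with extra elements `k_selected` and `bic` (the
#'   winning score).
#' @export
fit_gene_model <- function(emb, gene_weights, k_max_cap = 10L, seed = 0L, reg = NULL) {
  emb <- check_embedding(emb)
  if (sum(gene_weights > 0) < 1L) {
    stop_locat("gene has no expressing cells; untestable", "locat_untestable_error")
  }
  w <- gene_weights / sum(gene_weights)
  kmax <- gene_k_max(w, k_max_cap)
  # never propose more components than positively weighted cells
  kmax <- min(kmax, sum(w > 0))
  best <- NULL; best_bic <- Inf
  for (k in seq_len(kmax)) {
    m <- tryCatch(
      fit_wgmm(emb, w, k = k, seed = sub_seed(seed, 41L, k), reg = reg),
      locat_fit_error = function(e) NULL)
    if (is.null(m)) next
    b <- wgmm_bic(m, emb, w)
    if (b < best_bic) { best <- m; best_bic <- b }
  }
  best$bic <- best_bic
  best$k_selected <- best$k
  best
}
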