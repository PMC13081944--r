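# Concentration: density-contrast statistic and prevalence-calibrated p-value.

#' Raw concentration statistic
#'
#' Expression-weighted average, over expressing cells, of the prevalence-scaled
#' symmetric density contrast
#' `gamma_c = pi * (1 - pi) * (f_g - f_0) / (f_g + f_0)`.
#' Positive values indicate that the gene's fitted density exceeds the
#' background where the gene is expressed. Each `gamma_c` is bounded by
#' `pi * (1 - pi) <= 1/4`; the statistic is invariant to rescaling the weights.
#'
#' @param gene_weights Nonnegative expression weights over all cells.
#' @param f_g,f_0 Positive gene-specific and background densities at each cell.
#' @param prevalence Fraction of expressing cells, in `(0, 1)`.
#' @return The statistic `z_g` (a single number).
#' @export
contrast_statistic <- function(gene_weights, f_g, f_0, prevalence) {
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_locat("prevalence must lie strictly in (0, 1)", "locat_validation_error")
  }
  if (any(f_g <= 0) || any(f_0 <= 0)) {
    stop_locat("densities must be strictly positive (apply a floor upstream)",
               "locat_validation_error")
  }
  idx <- which(gene_weights > 0)
  if (!length(idx)) stop_locat("all gene weights are zero", "locat_validation_error")
  gamma <- prevalence * (1 - prevalence) *
    (f_g[idx] - f_0[idx]) / (f_g[idx] + f_0[idx])
  sum(gene_weights[idx] * gamma) / sum(gene_weights[idx])
}

# Pool of nonzero expression magnitudes from real genes with prevalence within
# a factor `band` of `target_prev`; falls back to all nonzero values.
magnitude_pool <- function(expr, target_prev, band = 1.5) {
  prev <- gene_prevalence(expr)
  near <- which(prev >= target_prev / band & prev <= target_prev * band & prev > 0)
  if (!length(near)) near <- which(prev > 0)
  vals <- unlist(lapply(near, function(g) {
    row <- expr[g, ]
    row[row > 0]
  }), use.names = FALSE)
  if (!length(vals)) vals <- 1
  vals
}

# One randomized pseudo-gene at a fixed prevalence: uniformly chosen support,
# weight magnitudes resampled from matched real genes.
pseudo_gene_weights <- function(n_cells, prevalence, pool, seed) {
  m <- max(1L, round(prevalence * n_cells))
  with_seed(seed, {
    idx <- sample.int(n_cells, m)
    w <- numeric(n_cells)
    w[idx] <- sample(pool, m, replace = TRUE)
    w
  })
}

#' Calibrate the concentration null across prevalence
#'
#' Builds the null location and scale of the raw concentration statistic as
#' functions of prevalence, from randomized pseudo-genes: at each grid
#' prevalence, `n_pseudo` pseudo-genes with uniformly random supports and
#' weight magnitudes resampled from prevalence-matched real genes are pushed
#' through the gene-density fit and [contrast_statistic()], and a robust
#' location/scale (median, 1.4826 * MAD) is recorded. Tested genes are later
#' standardized against the piecewise-linear (in log prevalence)
#' interpolation of these curves.
#'
#' @param emb Cells x d embedding.
#' @param background A `"background_density"` from [fit_background()].
#' @param expr Genes x cells expression matrix supplying magnitude pools.
#' @param grid_size Number of log-spaced prevalence grid points (>= 2).
#' @param n_pseudo Pseudo-genes per grid point (>= 20).
#' @param seed Master seed; pseudo-gene seeds are threaded deterministically.
#' @param max_freq Upper prevalence bound for testable genes.
#' @param grid_range Optional length-2 override of the grid's prevalence
#'   span; by default it covers the prevalences observed in `expr`, clamped
#'   to `[0.005, max_freq]`.
#' @param robust Use median/MAD (default) or mean/sd.
#' @param k_max_cap,reg Passed to [fit_gene_model()].
#'
#' @return An object of class `"null_calibration"`: tibble-backed grid with
#'   `prevalence`, `mu`, `sigma`, `n_pseudo`, plus the raw pseudo scores.
#' @export
calibrate_prevalence_null <- function(emb, background, expr,
                                      grid_size = 12L, n_pseudo = 100L,
                                      seed = 0L, max_freq = 0.9,
                                      grid_range = NULL, robust = TRUE,
                                      k_max_cap = 10L, reg = NULL) {
  emb <- check_embedding(emb)
  if (grid_size < 2L) stop_locat("grid_size must be >= 2", "locat_validation_error")
  if (n_pseudo < 20L) stop_locat("n_pseudo must be >= 20", "locat_validation_error")
  if (all(apply(emb, 2L, stats::var) < 1e-12)) {
    stop_locat("degenerate embedding: all points identical", "locat_calibration_error")
  }
  n <- nrow(emb)
  expr <- as_expression_matrix(expr)
  prev <- gene_prevalence(expr)
  prev <- prev[prev > 0]
  if (is.null(grid_range)) {
    lo <- max(min(prev), 0.005)
    hi <- min(max(prev), max_freq)
  } else {
    lo <- grid_range[1]; hi <- grid_range[2]
  }
  if (hi <= lo) { lo <- max(lo / 1.5, 1 / n); hi <- min(hi * 1.5, max_freq) }
  grid <- exp(seq(log(lo), log(hi), length.out = grid_size))
  f0 <- background$per_cell_density

  scores <- matrix(NA_real_, nrow = n_pseudo, ncol = grid_size)
  for (gi in seq_len(grid_size)) {
    pool <- magnitude_pool(expr, grid[gi])
    for (ri in seq_len(n_pseudo)) {
      ps <- sub_seed(seed, gi * n_pseudo + ri)
      w <- pseudo_gene_weights(n, grid[gi], pool, ps)
      model <- fit_gene_model(emb, w, k_max_cap = k_max_cap, seed = ps, reg = reg)
      fg <- wgmm_density(model, emb)
      pi_g <- mean(w > 0)
      scores[ri, gi] <- contrast_statistic(w, fg, f0, pi_g)
    }
  }
  if (robust) {
    mu <- apply(scores, 2L, stats::median)
    sigma <- apply(scores, 2L, stats::mad) # 1.4826 * MAD by default
  } else {
    mu <- colMeans(scores)
    sigma <- apply(scores, 2L, stats::sd)
  }
  sigma <- pmax(sigma, 1e-8)
  structure(list(
    grid = tibble(prevalence = grid, mu = mu, sigma = sigma, n_pseudo = n_pseudo),
    scores = scores, max_freq = max_freq, robust = robust
  ), class = "null_calibration")
}

interp_calibration <- function(cal, prevalence) {
  g <- cal$grid
  lp <- log(clamp(prevalence, min(g$prevalence), max(g$prevalence)))
  mu <- stats::approx(log(g$prevalence), g$mu, xout = lp, rule = 2, ties = "ordered")$y
  sigma <- stats::approx(log(g$prevalence), g$sigma, xout = lp, rule = 2, ties = "ordered")$y
  list(mu = mu, sigma = pmax(sigma, 1e-8))
}

#' Prevalence-adjusted concentration p-value
#'
#' Standardizes the raw statistic against the interpolated null curves and
#' reports the one-sided upper-tail normal p-value. Genes above the
#' calibration's `max_freq` are reported untested rather than erroring.
#'
#' @param z_raw Raw statistic from [contrast_statistic()].
#' @param prevalence The gene's prevalence.
#' @param cal A `"null_calibration"`.
#' @return A list with `z_raw`, `z_adj`, `p_conc`, `prevalence`, `tested`.
#' @export
concentration_pvalue <- function(z_raw, prevalence, cal) {
  if (prevalence > cal$max_freq) {
    return(list(z_raw = z_raw, z_adj = NA_real_, p_conc = NA_real_,
                prevalence = prevalence, tested = FALSE))
  }
  ms <- interp_calibration(cal, prevalence)
  z_adj <- (z_raw - ms$mu) / ms$sigma
  list(z_raw = z_raw, z_adj = z_adj,
       p_conc = stats::pnorm(z_adj, lower.tail = FALSE),
       prevalence = prevalence, tested = TRUE)
}
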