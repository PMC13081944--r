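# Secondary localization tests and baselines.

#' Likelihood-ratio test for localization
#'
#' Compares the gene-specific density fit to the background fit on the cells
#' expressing the gene: `Lambda = (2 / n_expr) * sum(log f_g - log f_0)`
#' (floored at 0), referred to a chi-square with `k0 - k_g + 1` degrees of
#' freedom (floored at 1). The per-cell normalization keeps the statistic
#' comparable across genes with different prevalences — and also bounds its
#' power, which is the point of carrying it as a baseline.
#'
#' @param emb Cells x d embedding.
#' @param gene_weights Nonnegative expression weights.
#' @param background A `"background_density"` from [fit_background()].
#' @param gene_model Optional pre-fitted gene `"wgmm"`; fitted when `NULL`.
#' @param min_cells Genes expressed in fewer cells are reported untested.
#' @param max_fraction Genes above this prevalence are reported untested.
#' @param seed,k_max_cap,reg Passed to [fit_gene_model()] when fitting.
#' @return A list with `statistic`, `df`, `p_lrt`, `tested`.
#' @export
likelihood_ratio_test <- function(emb, gene_weights, background,
                                  gene_model = NULL, min_cells = 10L,
                                  max_fraction = 0.9, seed = 0L,
                                  k_max_cap = 10L, reg = NULL) {
  emb <- check_embedding(emb)
  expressing <- which(gene_weights > 0)
  prevalence <- length(expressing) / length(gene_weights)
  if (length(expressing) < min_cells || prevalence > max_fraction) {
    return(list(statistic = NA_real_, df = NA_integer_, p_lrt = NA_real_,
                tested = FALSE))
  }
  if (is.null(gene_model)) {
    gene_model <- fit_gene_model(emb, gene_weights, k_max_cap = k_max_cap,
                                 seed = seed, reg = reg)
  }
  lf0 <- log(background$per_cell_density[expressing])
  lfg <- wgmm_density(gene_model, emb[expressing, , drop = FALSE], log = TRUE)
  lambda <- max(0, -2 * mean(lf0 - lfg))
  k0 <- background$k0
  df <- max(1L, as.integer(k0 - gene_model$k + 1L))
  list(statistic = lambda, df = df,
       p_lrt = stats::pchisq(lambda, df, lower.tail = FALSE), tested = TRUE)
}

# Cauchy-combined localization p-value and statistic for one weight vector
# against fixed background density and calibration (no penalties; used by the
# permutation diagnostic). The T statistic is kept because extreme p-values
# saturate at the clipping floor while T still orders them.
plain_p_loc <- function(emb, w, f0, cal, control, seed) {
  model <- fit_gene_model(emb, w, k_max_cap = control$k_max_cap,
                          seed = seed, reg = control$reg)
  fg <- wgmm_density(model, emb)
  prevalence <- mean(w > 0)
  conc <- concentration_pvalue(contrast_statistic(w, fg, f0, prevalence),
                               prevalence, cal)
  if (!conc$tested) return(c(p_loc = NA_real_, T = NA_real_))
  dep_cfg <- control$depletion
  if (is.null(dep_cfg$neff_cap)) dep_cfg$neff_cap <- length(w)
  dep <- depletion_pvalue(w, fg, f0, dep_cfg)
  cc <- cauchy_combine(conc$p_conc, dep$p_depl)
  c(p_loc = cc$p_loc, T = cc$T)
}

#' Permutation-based empirical localization p-value
#'
#' Builds a gene-specific null by rank-stratified weight shuffling: cells are
#' sorted by the gene's weights and split into `n_bins` rank bins; within
#' each bin weights are permuted among cells and then multiplied by
#' independent Exponential(1) factors (bootstrap-like variability); the gene
#' density is refitted and the Cauchy-combined localization p-value
#' recomputed. The empirical p-value uses the add-one rule
#' `(1 + #(null more extreme than observed)) / (n_replicates + 1)`, so it is
#' never exactly zero. Extremeness is compared on the combination statistic
#' (a strictly monotone transform of the combined p-value that does not
#' saturate numerically); exact ties resolve toward the observed pattern,
#' since each replicate is a noised copy of the gene itself.
#'
#' @param emb Cells x d embedding.
#' @param gene_weights Nonnegative expression weights.
#' @param background A `"background_density"`.
#' @param calibration A `"null_calibration"` for the concentration term.
#' @param n_replicates Number of null replicates (>= 20; default 100).
#' @param n_bins Rank bins (collapsed automatically for sparse genes).
#' @param seed Master seed.
#' @param control A [locat_control()] for the per-replicate scoring.
#' @return A list with `p_perm`, `observed` (the observed combined p-value)
#'   and `null` (vector of replicate values).
#' @export
permutation_pvalue <- function(emb, gene_weights, background, calibration,
                               n_replicates = 100L, n_bins = 10L, seed = 0L,
                               control = locat_control()) {
  if (n_replicates < 20L) stop_locat("n_replicates must be >= 20", "locat_validation_error")
  emb <- check_embedding(emb)
  f0 <- background$per_cell_density
  n <- length(gene_weights)
  n_expr <- sum(gene_weights > 0)
  n_bins <- max(1L, min(n_bins, n_expr))
  observed <- plain_p_loc(emb, gene_weights, f0, calibration, control,
                          seed = sub_seed(seed, 7L))
  ord <- order(gene_weights, decreasing = TRUE)
  bins <- split(ord, ceiling(seq_along(ord) / (n / n_bins)))
  null <- vapply(seq_len(n_replicates), function(r) {
    w_null <- with_seed(sub_seed(seed, 11L, r), {
      w <- gene_weights
      for (b in bins) w[b] <- w[sample(b)]
      w * stats::rexp(n)
    })
    plain_p_loc(emb, w_null, f0, calibration, control,
                seed = sub_seed(seed, 13L, r))
  }, c(p_loc = 0, T = 0))
  keep <- !is.na(null["T", ])
  # a null replicate counts as at least as extreme when its combined statistic
  # strictly exceeds the observed one; replicates are noised copies of the
  # gene itself, so exact ties resolve toward the observed pattern
  n_extreme <- sum(null["T", keep] > observed["T"])
  p <- (1 + n_extreme) / (sum(keep) + 1)
  list(p_perm = p, observed = observed[["p_loc"]],
       null = unname(null["p_loc", keep]))
}

#' Empirical rank p-values
#'
#' Converts raw per-gene scores to empirical significance by within-sample
#' ranking: `p = rank / (N + 1)` with average ranks for ties, rank 1 being
#' the strongest evidence under the declared direction. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Finite numeric scores.
#' @param direction `"lower_is_stronger"` or `"higher_is_stronger"`.
#' @return Numeric vector of p-values in `(0, 1)`.
#' @export
empirical_rank_pvalues <- function(scores,
                                   direction = c("lower_is_stronger",
                                                 "higher_is_stronger")) {
  direction <- match.arg(direction)
  if (!length(scores) || !all(is.finite(scores))) {
    stop_locat("scores must be finite and nonempty", "locat_validation_error")
  }
  s <- if (direction == "lower_is_stronger") scores else -scores
  rank(s, ties.method = "average") / (length(scores) + 1)
}

# Symmetric normalized Laplacian of the kNN graph on an embedding.
knn_laplacian <- function(emb, k = 15L) {
  n <- nrow(emb)
  nn <- knn_indices(emb, min(k, n - 1L))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  a <- (a + Matrix::t(a)) > 0 # symmetrize, unweighted
  a <- methods::as(a, "dMatrix") * 1
  deg <- pmax(Matrix::rowSums(a), 1)
  dinv <- Matrix::Diagonal(n, 1 / sqrt(deg))
  Matrix::Diagonal(n) - dinv %*% a %*% dinv
}

#' Spectral smoothness baseline (SpectralRH)
#'
#' Scores each gene by two geometric quantities on the k-nearest-neighbour
#' cell graph: the Rayleigh quotient of the centered, unit-norm expression
#' vector against the symmetric normalized Laplacian (graph smoothness) and
#' the Shannon entropy of its squared projections onto the first `m_eigs`
#' Laplacian eigenvectors (concentration of spectral energy). Both are
#' standardized against a per-gene permutation null (permuting a gene's
#' values across cells preserves its prevalence) and summed; lower scores
#' indicate smoother, more locally coherent — potentially localized —
#' expression.
#'
#' @param expr Genes x cells expression matrix.
#' @param emb Cells x d embedding.
#' @param m_eigs Number of low-frequency eigenvectors (default 96, reduced
#'   automatically to `n - 1`).
#' @param knn Neighbours in the cell graph (default 15).
#' @param n_null Permutations per gene for the null standardization.
#' @param seed Master seed.
#' @return Tibble with `gene_id`, `rayleigh`, `entropy`, `z_rayleigh`,
#'   `z_entropy`, `score` (`NA` for constant genes, which are untestable).
#' @export
spectral_rh <- function(expr, emb, m_eigs = 96L, knn = 15L, n_null = 50L,
                        seed = 0L) {
  expr <- as_expression_matrix(expr)
  emb <- check_embedding(emb, expr)
  n <- ncol(expr)
  m_eigs <- min(m_eigs, n - 1L)
  L <- knn_laplacian(emb, knn)
  Ld <- as.matrix(L)
  eig <- eigen(Ld, symmetric = TRUE)
  V <- eig$vectors[, order(eig$values)[seq_len(m_eigs)], drop = FALSE]

  gene_stats <- function(g) {
    g <- g - mean(g)
    nrm <- sqrt(sum(g^2))
    if (nrm < 1e-12) return(c(NA_real_, NA_real_))
    g <- g / nrm
    r <- as.numeric(crossprod(g, Ld %*% g))
    pr <- as.numeric(crossprod(V, g))^2
    tot <- sum(pr)
    h <- if (tot < 1e-300) NA_real_ else {
      p <- pr / tot
      p <- p[p > 0]
      -sum(p * log(p))
    }
    c(r, h)
  }

  tx <- Matrix::t(expr)
  out <- lapply(seq_len(nrow(expr)), function(gi) {
    g <- as.numeric(tx[, gi])
    obs <- gene_stats(g)
    if (anyNA(obs)) {
      return(tibble(gene_id = rownames(expr)[gi], rayleigh = NA_real_,
                    entropy = NA_real_, z_rayleigh = NA_real_,
                    z_entropy = NA_real_, score = NA_real_))
    }
    nulls <- with_seed(sub_seed(seed, 19L, gi), {
      vapply(seq_len(n_null), function(i) gene_stats(g[sample.int(n)]), numeric(2))
    })
    z <- (obs - rowMeans(nulls)) / pmax(apply(nulls, 1L, stats::sd), 1e-12)
    tibble(gene_id = rownames(expr)[gi], rayleigh = obs[1], entropy = obs[2],
           z_rayleigh = z[1], z_entropy = z[2], score = z[1] + z[2])
  })
  dplyr::bind_rows(out)
}

#' Temporal localization pattern over-representation
#'
#' Assigns each gene, from its per-timepoint localization calls, to one of
#' the `2^T - 1` admissible temporal patterns (genes localized at no
#' timepoint are excluded by construction) and contrasts observed pattern
#' frequencies with those expected were localization independent across
#' timepoints (product of marginal rates, renormalized over admissible
#' patterns). `delta = observed - expected` per pattern; its null
#' distribution is estimated by Monte Carlo resampling of flags with the
#' observed marginals. An overall chi-square test of independence across
#' patterns is included.
#'
#' @param localized_flags Logical matrix, genes x timepoints (>= 2 columns).
#' @param n_mc Monte Carlo replicates (default 10000; values below 100 warn).
#' @param seed Seed for the resampling.
#' @return A list: `patterns` (tibble with `pattern`, `n_genes`,
#'   `observed_freq`, `expected_freq`, `delta`), `null` (tibble of per-replicate
#'   mean and max-absolute null deltas), `chisq` (list with `statistic`, `df`,
#'   `p_value`), `n_retained`.
#' @export
temporal_pattern_delta <- function(localized_flags, n_mc = 10000L, seed = 0L) {
  flags <- as.matrix(localized_flags)
  mode(flags) <- "logical"
  tp <- ncol(flags)
  if (tp < 2L) stop_locat("need at least two timepoints", "locat_validation_error")
  if (n_mc < 100L) rlang::warn("n_mc < 100 gives a very coarse null")
  keep <- rowSums(flags) >= 1L
  flags <- flags[keep, , drop = FALSE]
  if (!nrow(flags)) stop_locat("no gene is localized at any timepoint", "locat_validation_error")
  ng <- nrow(flags)

  all_patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), tp)))[-1L, , drop = FALSE]
  all_patterns <- all_patterns[, rev(seq_len(tp)), drop = FALSE] # natural bit order
  pat_id <- apply(all_patterns, 1L, function(b) paste0(as.integer(b), collapse = ""))

  code <- function(m) apply(m, 1L, function(b) paste0(as.integer(b), collapse = ""))
  obs_counts <- table(factor(code(flags), levels = pat_id))
  obs_freq <- as.numeric(obs_counts) / ng

  marg <- colMeans(flags)
  exp_raw <- apply(all_patterns, 1L, function(b) prod(ifelse(b, marg, 1 - marg)))
  exp_freq <- exp_raw / sum(exp_raw)
  delta <- obs_freq - exp_freq

  null <- with_seed(seed, {
    res <- matrix(NA_real_, n_mc, 2L)
    for (i in seq_len(n_mc)) {
      sim <- matrix(stats::rbinom(ng * tp, 1L, rep(marg, each = ng)) == 1L, ng, tp)
      sim <- sim[rowSums(sim) >= 1L, , drop = FALSE]
      if (!nrow(sim)) { res[i, ] <- c(0, 0); next }
      f <- as.numeric(table(factor(code(sim), levels = pat_id))) / nrow(sim)
      d <- f - exp_freq
      res[i, ] <- c(mean(d), max(abs(d)))
    }
    res
  })

  expected_counts <- exp_freq * ng
  x2 <- sum((as.numeric(obs_counts) - expected_counts)^2 / pmax(expected_counts, 1e-12))
  df <- max(1L, length(pat_id) - 1L - tp)
  list(patterns = tibble(pattern = pat_id,
                         n_genes = as.integer(obs_counts),
                         observed_freq = obs_freq,
                         expected_freq = exp_freq,
                         delta = delta),
       null = tibble(mean_delta = null[, 1], max_abs_delta = null[, 2]),
       chisq = list(statistic = x2, df = df,
                    p_value = stats::pchisq(x2, df, lower.tail = FALSE)),
       n_retained = ng)
}
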