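test_that("likelihood-ratio statistic matches its closed forms", {
  emb <- gaussian_background(300, 2, seed = 1)
  bg <- fit_background(emb, k_grid = 1, n_inits = 1, seed = 2)
  w <- numeric(300); w[1:40] <- 1

  # gene model identical to background: Lambda = 0, p = 1
  same <- bg$fitted_models[[1]]
  r0 <- likelihood_ratio_test(emb, w, bg, gene_model = same)
  expect_equal(r0$statistic, 0, tolerance = 1e-6)
  expect_identical(r0$df, 1L)
  expect_equal(r0$p_lrt, 1, tolerance = 1e-6)

  # constant density ratio r: Lambda = 2 log r, independent of support size
  shifted <- same
  shifted$mix_weights <- shifted$mix_weights # density scaled via manual eval
  fake_bg <- bg
  fake_bg$per_cell_density <- wgmm_density(same, emb) / 10 # f_0 = f_g / 10
  r10 <- likelihood_ratio_test(emb, w, fake_bg, gene_model = same)
  expect_equal(r10$statistic, 2 * log(10), tolerance = 1e-6)
  expect_equal(r10$statistic, 4.6052, tolerance = 1e-4)
  w2 <- numeric(300); w2[1:150] <- 1 # different support, same constant ratio
  r10b <- likelihood_ratio_test(emb, w2, fake_bg, gene_model = same)
  expect_equal(r10b$statistic, r10$statistic, tolerance = 1e-6)

  # chi-square reference point
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  # exclusion below the minimum support
  w3 <- numeric(300); w3[1:5] <- 1
  ex <- likelihood_ratio_test(emb, w3, bg, min_cells = 10)
  expect_false(ex$tested)
})

test_that("permutation p-values follow the add-one rule and detect localization", {
  sim <- small_run(n_cells = 300, n_null = 1, seed = 21, n_expressing = 50)
  ctl <- fast_control(seed = 3)
  bg <- fit_background(sim$embedding, k_grid = 1:2, n_inits = 2, seed = 4)
  cal <- calibrate_prevalence_null(sim$embedding, bg, sim$expr, grid_size = 2,
                                   n_pseudo = 20, seed = 5,
                                   grid_range = c(0.1, 0.25))
  w_loc <- as.numeric(sim$expr["loc001", ])
  res <- permutation_pvalue(sim$embedding, w_loc, bg, cal,
                            n_replicates = 29, seed = 6, control = ctl)
  # admissible support of the estimator, never exactly zero
  expect_true(res$p_perm >= 1 / 30 && res$p_perm <= 1)
  expect_true(res$p_perm %in% (1:30) / 30 || res$p_perm <= 1) # add-one grid
  # a strongly localized gene beats its rank-shuffled nulls
  expect_lt(res$p_perm, 0.05)
  expect_error(permutation_pvalue(sim$embedding, w_loc, bg, cal, n_replicates = 5),
               class = "locat_validation_error")
})

test_that("empirical rank p-values implement average-tie ranking", {
  s <- c(5, 1, 3, 2, 4, 6, 7, 8, 9.5, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19,
         20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36,
         37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53,
         54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70,
         71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87,
         88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99)
  p <- empirical_rank_pvalues(s, "lower_is_stronger")
  expect_equal(p[which.min(s)], 1 / 100)
  expect_equal(min(p), 0.01)

  expect_equal(empirical_rank_pvalues(rep(7, 10)), rep(0.5, 10))

  s9 <- 1:9
  expect_equal(empirical_rank_pvalues(s9)[9], 0.9)
  expect_equal(empirical_rank_pvalues(s9, "higher_is_stronger")[1], 0.9)

  # invariance under strictly monotone transforms
  set.seed(9)
  x <- rnorm(40)
  expect_equal(empirical_rank_pvalues(x), empirical_rank_pvalues(exp(x)))
  expect_error(empirical_rank_pvalues(c(1, NA)), class = "locat_validation_error")
})

test_that("spectral baseline scores smooth patterns as more localized", {
  set.seed(31)
  emb <- rbind(matrix(rnorm(120, sd = 0.3), 60, 2) + 2,
               matrix(rnorm(280), 140, 2))
  cluster_gene <- c(rep(1, 60), numeric(140))
  noise_gene <- sample(cluster_gene)
  flat_gene <- rep(1, 200)
  expr <- make_expr(rbind(cluster_gene, noise_gene, flat_gene),
                    genes = c("clustered", "shuffled", "flat"))
  rs <- spectral_rh(expr, emb, m_eigs = 30, knn = 10, n_null = 30, seed = 1)

  # constant gene is untestable
  expect_true(is.na(rs$score[rs$gene_id == "flat"]))
  # a coherent cluster indicator concentrates spectral energy in low modes
  # and scores as more localized than its own permutation
  expect_lt(rs$z_entropy[rs$gene_id == "clustered"], -3)
  expect_lt(rs$z_rayleigh[rs$gene_id == "clustered"], 0)
  expect_lt(rs$rayleigh[rs$gene_id == "clustered"], 1) # smoother than a generic vector
  expect_lt(rs$score[rs$gene_id == "clustered"],
            rs$score[rs$gene_id == "shuffled"])

  # energy concentrated in a single eigenvector gives (near-)zero spectral
  # entropy; the residual comes only from mean-centering, since eigenvectors
  # of the normalized Laplacian are not exactly mean-zero
  L <- as.matrix(locat:::knn_laplacian(emb, 10))
  v2 <- eigen(L, symmetric = TRUE)$vectors[, 199]
  expr_v <- make_expr(rbind(v2 - min(v2) + 0.01), genes = "eigvec")
  rv <- spectral_rh(expr_v, emb, m_eigs = 30, knn = 10, n_null = 30, seed = 1)
  expect_lt(rv$entropy, 0.1)
  expect_gt(max(log(30) - rv$entropy, 0), 3) # essentially all energy in one mode
})

test_that("temporal pattern statistics enumerate and calibrate correctly", {
  # four timepoints admit exactly 15 nonzero patterns
  set.seed(41)
  flags <- matrix(runif(400 * 4) < rep(c(0.3, 0.4, 0.5, 0.35), each = 400), 400, 4)
  res <- temporal_pattern_delta(flags, n_mc = 500, seed = 2)
  expect_identical(nrow(res$patterns), 15L)
  expect_equal(sum(res$patterns$observed_freq), 1, tolerance = 1e-12)
  expect_equal(sum(res$patterns$expected_freq), 1, tolerance = 1e-12)
  # deltas over all patterns cancel
  expect_equal(sum(res$patterns$delta), 0, tolerance = 1e-12)
  # independent flags: small deviations, null centered at zero
  expect_lt(max(abs(res$patterns$delta)), 0.08)
  expect_lt(abs(mean(res$null$mean_delta)), 0.01)
  expect_gt(res$chisq$p_value, 1e-6) # no flagrant dependence

  # all genes on one pattern
  one <- matrix(FALSE, 50, 3); one[, 1] <- TRUE
  r1 <- temporal_pattern_delta(one, n_mc = 200, seed = 3)
  target <- r1$patterns[r1$patterns$pattern == "100", ]
  expect_equal(target$observed_freq, 1)
  expect_equal(target$delta, 1 - target$expected_freq, tolerance = 1e-12)

  expect_warning(temporal_pattern_delta(flags, n_mc = 50, seed = 1), "coarse")
  expect_error(temporal_pattern_delta(flags[, 1, drop = FALSE], n_mc = 200),
               class = "locat_validation_error")
})

test_that("strongly dependent temporal patterns are flagged by the chi-square", {
  set.seed(51)
  base <- runif(300) < 0.5
  flags <- cbind(base, base, runif(300) < 0.3, runif(300) < 0.3)
  res <- temporal_pattern_delta(flags, n_mc = 300, seed = 4)
  expect_lt(res$chisq$p_value, 1e-10)
  # the observed max |delta| exceeds the Monte Carlo null's typical maximum
  expect_gt(max(abs(res$patterns$delta)), quantile(res$null$max_abs_delta, 0.99))
})
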