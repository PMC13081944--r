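test_that("Kish effective sample size matches its closed forms", {
  expect_equal(kish_neff(rep(0.37, 25)), 25)
  expect_equal(kish_neff(c(1, numeric(9))), 1)
  expect_equal(kish_neff(c(0.5, 0.5)), 2)
  expect_equal(kish_neff(c(0.9, 0.1)), 1 / 0.82)
  expect_equal(kish_neff(c(0.9, 0.1)), 1.2195, tolerance = 1e-4)
  set.seed(1)
  w <- rexp(40)
  expect_gte(kish_neff(w), 1)
  expect_lte(kish_neff(w), 40)
  expect_error(kish_neff(numeric(5)), class = "locat_validation_error")
  expect_error(kish_neff(c(-1, 2)), class = "locat_validation_error")
})

test_that("depletion tail reproduces binomial and beta-binomial reference values", {
  # identical densities: the region is empty, the contrast inadmissible
  n <- 100
  f0 <- rep(0.3, n)
  w <- c(rep(1, 20), numeric(80))
  r <- depletion_tail(w, f0, f0, lam = 2)
  expect_identical(r$region_size, 0L)
  expect_false(r$admissible)
  expect_equal(r$p_tail, 1)

  # rho = 0 reduces to the binomial lower tail: 0.7^20
  expect_equal(stats::pbinom(0, 20, 0.3), 0.7^20)
  expect_equal(locat:::betabinom_lower_tail(0, 20, 0.3 * 49, 0.7 * 49),
               0.00283440698383752, tolerance = 1e-10) # overdispersed reference
  # overdispersion inflates the lower tail relative to the binomial
  expect_gt(locat:::betabinom_lower_tail(0, 20, 0.3 * 49, 0.7 * 49), 0.7^20)
})

test_that("beta-binomial tail matches independent reference values to 1e-10", {
  # frozen from an independent implementation (scipy.stats.betabinom.cdf)
  cases <- list(
    list(k = 0, n = 20, p0 = 0.3, rho = 0.02, p = 0.00283440698383752),
    list(k = 3, n = 20, p0 = 0.3, rho = 0.02, p = 0.150142585827819),
    list(k = 5, n = 46, p0 = 0.35, rho = 0.02, p = 0.00416535050571289),
    list(k = 10, n = 50, p0 = 0.5, rho = 0.1, p = 0.0452493049113036),
    list(k = 2, n = 12, p0 = 0.9, rho = 0.02, p = 6.71572891799468e-07),
    list(k = 7, n = 30, p0 = 0.25, rho = 0.05, p = 0.536832154996135))
  for (cs in cases) {
    conc <- 1 / cs$rho - 1
    got <- locat:::betabinom_lower_tail(cs$k, cs$n, cs$p0 * conc, (1 - cs$p0) * conc)
    expect_equal(got, cs$p, tolerance = 1e-10)
  }
})

test_that("depletion regions nest and masses decrease in the contrast threshold", {
  set.seed(5)
  n <- 400
  f0 <- exp(rnorm(n))
  fg <- exp(rnorm(n, -0.3))
  w <- numeric(n); w[sample(n, 60)] <- rexp(60)
  cfg <- depletion_control(neff_cap = n)
  scan <- depletion_pvalue(w, fg, f0, cfg)$scan
  expect_true(all(diff(scan$region_size) <= 0))
  expect_true(all(diff(scan$beta0) <= 1e-12))
  expect_true(all(diff(scan$betag) <= 1e-12))
  expect_true(all(scan$beta0 >= 0 & scan$beta0 <= 1))
  expect_true(all(scan$k_obs <= scan$n_trials))
})

test_that("tail probability is non-increasing in the effective trial count", {
  # fixed beta0 > betag: more effective trials can only sharpen the tail
  p_for_n <- function(n_trials) {
    conc <- 1 / 0.02 - 1
    locat:::betabinom_lower_tail(round(0.1 * n_trials), n_trials, 0.3 * conc, 0.7 * conc)
  }
  ps <- sapply(c(10, 20, 40, 80, 160), p_for_n)
  expect_true(all(diff(ps) < 0))
})

test_that("Sidak-form scan adjustment behaves per its closed form", {
  set.seed(6)
  n <- 500
  emb_d <- sqrt(rowSums(matrix(rnorm(n * 2), n, 2)^2))
  f0 <- exp(-emb_d)
  fg <- exp(-2 * emb_d) # gene concentrated: depleted from the f0-heavy tail? inverted below
  w <- numeric(n); w[order(emb_d)[1:50]] <- 1 # expressing cells at the center
  res <- depletion_pvalue(w, exp(-emb_d^2), f0, depletion_control(neff_cap = n))
  adm <- res$scan[res$scan$admissible, ]
  if (nrow(adm) > 0) {
    expect_equal(res$p_depl, 1 - (1 - min(adm$p_tail))^nrow(adm), tolerance = 1e-9)
    expect_gte(res$p_depl, min(adm$p_tail))
  }

  # closed-form checks of the adjustment itself
  expect_equal(1 - (1 - 0.01)^5, 0.04900995, tolerance = 1e-7)
  # a single admissible contrast leaves the minimum untouched
  one <- depletion_control(lambda_grid = 2, neff_cap = n)
  r1 <- depletion_pvalue(w, exp(-emb_d^2), f0, one)
  if (nrow(r1$scan[r1$scan$admissible, ]) == 1) {
    expect_equal(r1$p_depl, r1$scan$p_tail[r1$scan$admissible])
  }

  # no admissible contrast: p = 1
  w_match <- numeric(n); w_match[sample(n, 50)] <- 1
  r_null <- depletion_pvalue(w_match, f0, f0, depletion_control(neff_cap = n))
  expect_equal(r_null$p_depl, 1)
  expect_null(r_null$best_contrast)
})

test_that("pseudo-genes drawn from the background rarely show depletion", {
  emb <- gaussian_background(500, 2, seed = 77)
  bg <- fit_background(emb, k_grid = 1:2, n_inits = 2, seed = 1)
  f0 <- bg$per_cell_density
  hits <- 0
  n_rep <- 40
  for (i in 1:n_rep) {
    w <- numeric(500)
    set.seed(500 + i)
    w[sample(500, 60)] <- rlnorm(60, 0, 0.5)
    m <- fit_gene_model(emb, w, seed = 600 + i)
    fg <- wgmm_density(m, emb)
    p <- depletion_pvalue(w, fg, f0, depletion_control(neff_cap = 500))$p_depl
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})
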