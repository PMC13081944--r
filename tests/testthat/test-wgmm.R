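test_that("k = 1 weighted fit has the closed-form weighted mean and covariance", {
  set.seed(11)
  x <- matrix(rnorm(200), 100, 2)
  w <- runif(100)
  m <- fit_wgmm(x, w, k = 1, seed = 1, reg = 1e-8)
  wn <- w / sum(w)
  mu <- colSums(x * wn)
  cen <- sweep(x, 2, mu)
  sig <- crossprod(sqrt(wn) * cen) + diag(1e-8, 2)
  expect_equal(as.numeric(m$means), mu, tolerance = 1e-8)
  expect_equal(m$covariances[[1]], sig, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(m$mix_weights), 1, tolerance = 1e-9)

  # weight mass on a single point collapses the mean onto it
  w1 <- c(1, rep(0, 99))
  m1 <- fit_wgmm(x, w1, k = 1, seed = 1, reg = 1e-6)
  expect_equal(as.numeric(m1$means), x[1, ], tolerance = 1e-8)
})

test_that("EM recovers two well-separated clusters and agrees with mclust", {
  set.seed(21)
  x <- rbind(matrix(rnorm(400), 200, 2) + 4, matrix(rnorm(400), 200, 2) - 4)
  m <- fit_wgmm(x, k = 2, seed = 2)
  centers <- m$means[order(m$means[, 1]), ]
  expect_lt(max(abs(centers[1, ] - c(-4, -4))), 0.2)
  expect_lt(max(abs(centers[2, ] - c(4, 4))), 0.2)
  expect_equal(sort(m$mix_weights), c(0.5, 0.5), tolerance = 0.05)

  # independent cross-check: unweighted log-likelihood against mclust VVV
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  ll_ours <- sum(wgmm_density(m, x, log = TRUE))
  expect_equal(ll_ours, mc$loglik, tolerance = 0.01)
})

test_that("weighted log-likelihood is non-decreasing over EM iterations", {
  for (s in 1:5) {
    set.seed(30 + s)
    x <- rbind(matrix(rnorm(120), 60, 2), matrix(rnorm(120), 60, 2) + 2)
    w <- rexp(120)
    m <- fit_wgmm(x, w, k = 3, seed = s)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("fit errors on too few positive weights and non-finite input", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_wgmm(x, c(1, 1, rep(0, 8)), k = 3), class = "locat_fit_error")
  x[1, 1] <- NA
  expect_error(fit_wgmm(x, k = 1), class = "locat_validation_error")
})

test_that("mixture density integrates to one over a bounding box", {
  set.seed(41)
  x <- matrix(rnorm(300), 150, 2)
  m <- fit_wgmm(x, k = 2, seed = 3)
  # Monte Carlo integral over [-8, 8]^2
  u <- matrix(runif(2e5, -8, 8), ncol = 2)
  integral <- mean(wgmm_density(m, u)) * 16^2
  expect_equal(integral, 1, tolerance = 0.05)
})

test_that("BIC is deterministic, prefers parsimony, and detects real structure", {
  set.seed(51)
  x1 <- matrix(rnorm(1000), 500, 2)
  f1 <- fit_wgmm(x1, k = 1, seed = 9)
  f1b <- fit_wgmm(x1, k = 1, seed = 9)
  expect_identical(wgmm_bic(f1, x1), wgmm_bic(f1b, x1))
  f4 <- fit_wgmm(x1, k = 4, seed = 9)
  expect_lt(wgmm_bic(f1, x1), wgmm_bic(f4, x1)) # single Gaussian: k = 1 wins

  x2 <- rbind(matrix(rnorm(500), 250, 2) - 5, matrix(rnorm(500), 250, 2) + 5)
  g1 <- fit_wgmm(x2, k = 1, seed = 9)
  g2 <- fit_wgmm(x2, k = 2, seed = 9)
  expect_lt(wgmm_bic(g2, x2), wgmm_bic(g1, x2)) # separation: k = 2 wins
})

test_that("background fit selects k, averages initialisations, floors densities", {
  emb <- gaussian_background(400, 2, seed = 61)
  bg <- fit_background(emb, k_grid = 1:3, n_inits = 3, seed = 6)
  expect_identical(bg$k0, 1L) # single-Gaussian embedding
  expect_true(all(bg$per_cell_density > 0))
  expect_length(bg$per_cell_density, 400)

  one <- fit_background(emb, k_grid = 1, n_inits = 1, seed = 6)
  expect_equal(one$per_cell_density,
               wgmm_density(one$fitted_models[[1]], emb))
})

test_that("background averaging across initialisations reduces density variance", {
  emb <- gaussian_background(300, 2, seed = 71)
  dens_at <- function(n_inits, seed) {
    fit_background(emb, k_grid = 2, n_inits = n_inits, seed = seed)$per_cell_density
  }
  d1 <- sapply(1:6, function(s) dens_at(1, 100 + s))
  d5 <- sapply(1:6, function(s) dens_at(5, 200 + s))
  sd1 <- mean(apply(d1, 1, sd))
  sd5 <- mean(apply(d5, 1, sd))
  expect_lt(sd5, sd1)
})

test_that("gene model adapts component count to support and is deterministic", {
  emb <- gaussian_background(300, 2, seed = 81)
  w3 <- numeric(300); w3[1:3] <- 1
  m3 <- fit_gene_model(emb, w3, seed = 4)
  expect_identical(m3$k_selected, 1L) # support rule forces one component

  # two compact well-separated modes with ample support select two components
  emb2 <- rbind(matrix(rnorm(200, sd = 0.2), 100, 2) + 3,
                matrix(rnorm(200, sd = 0.2), 100, 2) - 3,
                gaussian_background(200, 2, seed = 82))
  w2 <- c(rep(1, 200), numeric(200))
  m2 <- fit_gene_model(emb2, w2, seed = 4)
  expect_identical(m2$k_selected, 2L)

  again <- fit_gene_model(emb2, w2, seed = 4)
  expect_equal(m2$means, again$means)
  expect_equal(m2$bic, again$bic)
  expect_error(fit_gene_model(emb, numeric(300), seed = 1),
               class = "locat_untestable_error")
})
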