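test_that("Gaussian background has the right moments and is reproducible", {
  emb <- gaussian_background(1500, 2, seed = 4)
  expect_identical(dim(emb), c(1500L, 2L))
  expect_true(all(abs(colMeans(emb)) < 3 / sqrt(1500)))
  expect_true(all(apply(emb, 2, var) > 0.85 & apply(emb, 2, var) < 1.15))
  expect_identical(emb, gaussian_background(1500, 2, seed = 4))
  expect_false(identical(emb, gaussian_background(1500, 2, seed = 5)))
  expect_error(gaussian_background(5, 2), class = "locat_validation_error")
})

test_that("tiny radius selects the nearest neighbours of the center", {
  emb <- gaussian_background(500, 2, seed = 14)
  center <- c(0.5, -0.25)
  w <- simulate_localized_gene(emb, center = center, radius = 1e-9,
                               n_expressing = 25, seed = 3)
  support <- which(w > 0)
  d <- sqrt(colSums((t(emb) - center)^2))
  expect_setequal(support, order(d)[1:25])
  expect_true(all(w[support] > 0))
  expect_identical(sum(w > 0), 25L)
})

test_that("two far-apart modes give two disjoint compact clumps", {
  emb <- rbind(gaussian_background(400, 2, seed = 24),
               gaussian_background(400, 2, seed = 25) + 8)
  w <- simulate_localized_gene(emb, center = c(0, 0), radius = 0.4,
                               n_expressing = 60, n_modes = 2, mode_spread = 4,
                               jitter = 0, seed = 5)
  pos <- emb[w > 0, ]
  cl <- kmeans(pos, centers = 2, nstart = 5)
  # both clumps tight relative to their separation
  expect_gt(sqrt(sum((cl$centers[1, ] - cl$centers[2, ])^2)), 2)
  expect_lt(max(sqrt(cl$withinss / cl$size)), 1)
})

test_that("very large radius yields a background-like expressing set", {
  # radial distribution of expressing cells matches the background when the
  # dispersion ball swallows the cloud
  ps <- sapply(1:6, function(s) {
    emb <- gaussian_background(1500, 2, seed = 30 + s)
    w <- simulate_localized_gene(emb, center = c(0, 0), radius = 3,
                                 n_expressing = 100, seed = 40 + s)
    r_all <- sqrt(rowSums(emb^2))
    suppressWarnings(ks.test(r_all[w > 0], r_all[w == 0])$p.value)
  })
  expect_gt(mean(ps), 0.05)
})

test_that("perturbations hit exact counts and keep invariants", {
  emb <- gaussian_background(600, 2, seed = 44)
  w <- simulate_localized_gene(emb, radius = 0.3, n_expressing = 100, seed = 6)

  expect_identical(perturb_gene(w, "subsample", 0, seed = 1), w)
  expect_identical(perturb_gene(w, "redistribute_background", 0, seed = 1), w)

  sub <- perturb_gene(w, "subsample", 0.5, seed = 2)
  expect_identical(sum(sub > 0), 50L)
  expect_true(all(sub[sub > 0] == w[sub > 0])) # survivors keep their weights

  red <- perturb_gene(w, "redistribute_background", 0.5, seed = 3)
  expect_identical(sum(red > 0), 100L) # expressing count fixed
  expect_equal(sort(red[red > 0]), sort(w[w > 0])) # magnitudes preserved
  moved <- sum(w > 0 & red == 0)
  expect_identical(moved, 50L)

  full <- perturb_gene(w, "redistribute_background", 1, seed = 4)
  expect_identical(sum(full > 0), 100L)
  expect_lte(sum(full > 0 & w > 0), 5) # support almost completely relocated
})

test_that("simulated datasets carry coherent truth labels and metadata", {
  sim <- simulate_dataset(n_cells = 300, n_localized = 2, n_null = 3,
                          radius = 0.3, n_expressing = 40, seed = 8)
  expect_identical(dim(sim$expr), c(5L, 300L))
  expect_identical(sum(sim$truth$localized), 2L)
  expect_true(all(Matrix::rowSums(sim$expr > 0) == 40))
  expect_identical(rownames(sim$embedding), colnames(sim$expr))
  # reproducible end to end
  sim2 <- simulate_dataset(n_cells = 300, n_localized = 2, n_null = 3,
                           radius = 0.3, n_expressing = 40, seed = 8)
  expect_identical(as.matrix(sim$expr), as.matrix(sim2$expr))
})

test_that("final p-values separate planted from null genes (easy regime)", {
  scores <- list()
  for (rep in 1:3) {
    sim <- simulate_dataset(n_cells = 500, n_localized = 1, n_null = 8,
                            radius = 0.3, n_expressing = 80, seed = 60 + rep)
    fit <- locat(sim$expr, sim$embedding, control = fast_control(seed = rep))
    res <- dplyr::left_join(fit$results, sim$truth, by = "gene_id")
    scores[[rep]] <- res
  }
  all_res <- dplyr::bind_rows(scores)
  pos <- all_res$p_tilde[all_res$localized]
  neg <- all_res$p_tilde[!all_res$localized]
  auroc <- mean(outer(pos, neg, `<`)) # P(planted ranks ahead of null)
  expect_gt(auroc, 0.95)
})

test_that("benchmark runner produces a complete, summarised power table", {
  b <- benchmark_power("radius", grid = c(0.3, 2.5), n_replicates = 2,
                       methods = c("locat", "lrt"), seed = 5,
                       n_cells = 400, n_expressing = 60)
  expect_identical(nrow(b$results), 2L * 2L * 2L)
  expect_true(all(b$results$p >= 0 & b$results$p <= 1, na.rm = TRUE))
  expect_identical(nrow(b$summary), 4L)
  expect_identical(sort(unique(b$summary$method)), c("locat", "lrt"))
  expect_s3_class(autoplot(b), "ggplot")
  # easy level significant, hopeless level not, for the localization test
  s <- b$summary[b$summary$method == "locat", ]
  expect_lt(s$median_p[s$level == 0.3], 0.05)
  expect_gt(s$median_p[s$level == 2.5], 0.05)
})
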