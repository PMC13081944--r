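# Synthetic embeddings, localized genes and power benchmarks.

#' Standard Gaussian background embedding
#'
#' `n_cells` i.i.d. draws from a unit-variance d-variate Gaussian — the
#' structureless background against which simulated localized genes are
#' planted.
#'
#' @param n_cells Number of cells (>= 10; benchmarks use 1500).
#' @param d Embedding dimension (benchmarks use 2).
#' @param seed Integer seed.
#' @return An n x d matrix.
#' @export
gaussian_background <- function(n_cells = 1500L, d = 2L, seed = 0L) {
  if (n_cells < 10L) stop_locat("n_cells must be >= 10", "locat_validation_error")
  with_seed(seed, matrix(stats::rnorm(n_cells * d), n_cells, d))
}

# Per-axis spread of the embedding, used to express jitter as a percentage.
background_range <- function(emb) {
  mean(apply(emb, 2L, function(x) diff(range(x))))
}

#' Plant a localized gene on an embedding
#'
#' Draws `n_expressing` expressing cells from a compact neighbourhood: cells
#' lying within distance `radius` of a mode center are sampled uniformly
#' (the gene's share of a mode falls back to the nearest cells when the ball
#' holds too few), and the selected cells receive lognormal expression
#' magnitudes. Outside the ball the gene is truly absent, so small radii
#' give both concentration and genuine depletion; as `radius` grows the
#' neighbourhood swallows the background and the expressing cells become a
#' uniform background subsample. As `radius -> 0` the expressing cells are
#' exactly the nearest neighbours of the centers. `jitter` spreads the
#' expressing cells around their mode: each cell's target position receives
#' an independent Gaussian displacement with standard deviation
#' `jitter / 100` times the background range, so growing jitter makes each
#' mode progressively more diffuse until the pattern merges with the
#' background.
#'
#' @param emb Cells x d embedding.
#' @param center Mode center (length-d vector). By default the position of a
#'   uniformly chosen background cell — a localized subpopulation generically
#'   sits away from the embedding's center of mass, and replicate genes land
#'   in different places; for `n_modes > 1` each mode gets its own randomly
#'   chosen cell as center.
#' @param radius Positive dispersion radius of the expression neighbourhood.
#' @param n_expressing Number of expressing cells.
#' @param n_modes Number of modes; for `n_modes > 1` the modes sit evenly on
#'   a circle of radius `mode_spread` around `center` (random orientation).
#' @param jitter Positional jitter as a percentage of the background range.
#' @param seed Integer seed.
#' @param mode_spread Distance of multimodal centers from `center`.
#' @param meanlog,sdlog Lognormal magnitude parameters.
#' @return Numeric weight vector over cells (zero outside the support).
#' @export
simulate_localized_gene <- function(emb, center = NULL, radius = 0.3,
                                    n_expressing = 100L, n_modes = 1L,
                                    jitter = 0, seed = 0L, mode_spread = 1.5,
                                    meanlog = 0, sdlog = 0.5) {
  emb <- check_embedding(emb)
  n <- nrow(emb); d <- ncol(emb)
  if (n_expressing > n) stop_locat("n_expressing exceeds n_cells", "locat_validation_error")
  if (radius <= 0) stop_locat("radius must be positive", "locat_validation_error")
  rng <- background_range(emb)
  with_seed(seed, {
    if (is.null(center)) {
      # random cell positions as mode centers
      centers <- emb[sample.int(n, n_modes), , drop = FALSE]
    } else {
      centers <- matrix(rep(center, each = n_modes), n_modes, d)
      if (n_modes > 1L) {
        theta0 <- stats::runif(1, 0, 2 * pi)
        theta <- theta0 + 2 * pi * (seq_len(n_modes) - 1) / n_modes
        offset <- cbind(cos(theta), sin(theta), matrix(0, n_modes, max(0, d - 2)))
        centers <- centers + mode_spread * offset[, seq_len(d), drop = FALSE]
      }
    }
    # split the support roughly evenly across modes
    counts <- diff(round(seq(0, n_expressing, length.out = n_modes + 1L)))
    sigma_j <- jitter / 100 * rng
    support <- integer(0)
    for (m in seq_len(n_modes)) {
      take <- counts[m]
      if (take == 0L) next
      dist_m <- sqrt(rowSums(sweep(emb, 2L, centers[m, ])^2))
      avail <- setdiff(seq_len(n), support)
      inside <- avail[dist_m[avail] <= radius]
      # uniform draw among the cells inside the ball; when the ball holds too
      # few cells, fall back to the nearest ones
      base <- if (length(inside) >= take) sample(inside, take) else {
        avail[order(dist_m[avail])[seq_len(take)]]
      }
      if (sigma_j == 0) {
        support <- c(support, base)
        next
      }
      # jitter: displace each selected cell and re-snap to the nearest
      # still-unused cell, diffusing the mode into its surroundings
      targets <- emb[base, , drop = FALSE] +
        matrix(stats::rnorm(take * d, sd = sigma_j), take, d)
      d2 <- outer(rowSums(targets^2), rowSums(emb^2), `+`) -
        2 * tcrossprod(targets, emb)
      if (length(support)) d2[, support] <- Inf
      for (i in seq_len(take)) {
        j <- which.min(d2[i, ])
        support <- c(support, j)
        d2[, j] <- Inf
      }
    }
    w <- numeric(n)
    w[support] <- stats::rlnorm(n_expressing, meanlog, sdlog)
    w
  })
}

#' Perturb a template gene
#'
#' Two controlled degradations of a gene's expression pattern:
#' `"subsample"` retains a uniformly chosen `round((1 - level) * n_expr)`
#' expressing cells and zeroes the rest; `"redistribute_background"` keeps
#' the expressing-cell count fixed but moves a fraction `level` of the
#' expressing cells' weights onto uniformly chosen non-expressing cells,
#' diluting localization into the background.
#'
#' @param gene_weights Weight vector over cells.
#' @param mode `"subsample"` or `"redistribute_background"`.
#' @param level Perturbation level in `[0, 1]`; 0 is the identity.
#' @param seed Integer seed.
#' @return Perturbed weight vector.
#' @export
perturb_gene <- function(gene_weights,
                         mode = c("subsample", "redistribute_background"),
                         level, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(level >= 0, level <= 1)
  if (level == 0) return(gene_weights)
  expressing <- which(gene_weights > 0)
  n_expr <- length(expressing)
  with_seed(seed, {
    w <- gene_weights
    if (mode == "subsample") {
      keep_n <- round((1 - level) * n_expr)
      drop <- if (keep_n == 0L) expressing else {
        setdiff(expressing, sample(expressing, keep_n))
      }
      w[drop] <- 0
    } else {
      move_n <- round(level * n_expr)
      if (move_n > 0L) {
        from <- sample(expressing, move_n)
        pool <- which(gene_weights == 0)
        to <- sample(pool, min(move_n, length(pool)))
        w[to] <- w[from[seq_along(to)]]
        w[from[seq_along(to)]] <- 0
      }
    }
    w
  })
}

#' Simulate a dataset with known ground truth
#'
#' A Gaussian background embedding carrying `n_localized` planted localized
#' genes and `n_null` prevalence-matched null genes (uniform random supports
#' with the same magnitude distribution).
#'
#' @param n_cells,d,seed Background parameters, see [gaussian_background()].
#' @param n_localized,n_null Gene counts per class.
#' @param radius,n_expressing,n_modes,jitter Localized-gene parameters, see
#'   [simulate_localized_gene()].
#' @return A list: `embedding`, `expr` (sparse genes x cells matrix),
#'   `truth` (tibble with `gene_id`, `localized`), `params`.
#' @export
simulate_dataset <- function(n_cells = 1500L, d = 2L, n_localized = 1L,
                             n_null = 0L, radius = 0.3, n_expressing = 100L,
                             n_modes = 1L, jitter = 0, seed = 0L) {
  emb <- gaussian_background(n_cells, d, seed = sub_seed(seed, 101L))
  genes <- list(); ids <- character(); truth <- logical()
  for (i in seq_len(n_localized)) {
    genes[[length(genes) + 1L]] <-
      simulate_localized_gene(emb, radius = radius, n_expressing = n_expressing,
                              n_modes = n_modes, jitter = jitter,
                              seed = sub_seed(seed, 103L, i))
    ids <- c(ids, sprintf("loc%03d", i)); truth <- c(truth, TRUE)
  }
  for (i in seq_len(n_null)) {
    w <- with_seed(sub_seed(seed, 107L, i), {
      v <- numeric(n_cells)
      v[sample.int(n_cells, n_expressing)] <- stats::rlnorm(n_expressing, 0, 0.5)
      v
    })
    genes[[length(genes) + 1L]] <- w
    ids <- c(ids, sprintf("null%03d", i)); truth <- c(truth, FALSE)
  }
  expr <- methods::as(do.call(rbind, genes), "CsparseMatrix")
  dimnames(expr) <- list(ids, sprintf("cell%04d", seq_len(n_cells)))
  rownames(emb) <- colnames(expr)
  list(embedding = emb, expr = expr,
       truth = tibble(gene_id = ids, localized = truth),
       params = list(n_cells = n_cells, d = d, radius = radius,
                     n_expressing = n_expressing, n_modes = n_modes,
                     jitter = jitter, seed = seed))
}

#' Benchmark-scale pipeline configuration
#'
#' The pipeline defaults scaled for simulation sweeps: a standard Gaussian
#' background needs few candidate components (`k_grid` 1:3, 3 averaged
#' refits), planted genes have at most a few compact modes (`k_max_cap` 5),
#' and the calibration grid only has to bracket the prevalences of the genes
#' under test (4 grid points, 50 pseudo-genes each).
#'
#' @param ... Overrides passed to [locat_control()].
#' @return A `"locat_control"`.
#' @export
benchmark_control <- function(...) {
  locat_control(k_grid = 1:3, n_inits = 3L, grid_size = 4L, n_pseudo = 50L,
                k_max_cap = 5L, ...)
}

# Build the per-level gene weights for one benchmark replicate.
scenario_genes <- function(scenario, grid, emb, n_expressing, seed) {
  base_seed <- sub_seed(seed, 211L)
  if (scenario %in% c("subsample", "redistribute")) {
    template <- simulate_localized_gene(emb, radius = 0.3,
                                        n_expressing = n_expressing,
                                        seed = base_seed)
    mode <- if (scenario == "subsample") "subsample" else "redistribute_background"
    return(lapply(seq_along(grid), function(i) {
      perturb_gene(template, mode, grid[i], seed = sub_seed(seed, 223L, i))
    }))
  }
  lapply(seq_along(grid), function(i) {
    lseed <- sub_seed(seed, 227L, i)
    switch(scenario,
      radius = simulate_localized_gene(emb, radius = grid[i],
                                       n_expressing = n_expressing, seed = lseed),
      sample_size = simulate_localized_gene(emb, radius = 0.3,
                                            n_expressing = as.integer(grid[i]),
                                            seed = lseed),
      jitter = simulate_localized_gene(emb, radius = 0.3, n_modes = 3L,
                                       n_expressing = n_expressing,
                                       jitter = grid[i], seed = lseed))
  })
}

#' Power benchmark over a simulation sweep
#'
#' For each replicate, draws a fresh Gaussian background, fits the background
#' density and concentration calibration once, plants one localized gene per
#' grid level according to the scenario, and records each method's p-value.
#' Scenarios: `"radius"` (dispersion radius sweep), `"sample_size"`
#' (expressing-cell count sweep at radius 0.3), `"jitter"` (trimodal gene,
#' positional jitter sweep), `"subsample"` and `"redistribute"` (template
#' gene perturbations). Methods: the localization pipeline (`"locat"`), the
#' likelihood-ratio baseline (`"lrt"`), and the permutation diagnostic
#' (`"permutation"`, expensive).
#'
#' @param scenario One of the five scenario names.
#' @param grid Numeric vector of levels (radii, expressing-cell counts,
#'   jitter percentages, or perturbation fractions).
#' @param n_replicates Replicates per level (default 20).
#' @param methods Subset of `c("locat", "lrt", "permutation")`.
#' @param seed Master seed.
#' @param n_cells,d,n_expressing Simulation parameters.
#' @param control Pipeline configuration (default [benchmark_control()]).
#' @param n_perm_replicates Replicates for the permutation method.
#' @return An object of class `"locat_power"`: `results` (long tibble:
#'   `level`, `replicate`, `method`, `p`), `summary` (per level x method
#'   median p and fraction significant at 0.05), `crossing` (per method the
#'   first grid level at which the median p exceeds 0.05), `scenario`.
#' @export
benchmark_power <- function(scenario = c("radius", "sample_size", "jitter",
                                         "subsample", "redistribute"),
                            grid, n_replicates = 20L,
                            methods = c("locat", "lrt"), seed = 0L,
                            n_cells = 1500L, d = 2L, n_expressing = 100L,
                            control = benchmark_control(),
                            n_perm_replicates = 100L) {
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, c("locat", "lrt", "permutation"), several.ok = TRUE)
  if (!length(grid)) stop_locat("grid must be nonempty", "locat_validation_error")

  rows <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- sub_seed(seed, 1009L, r)
    emb <- gaussian_background(n_cells, d, seed = sub_seed(rseed, 1L))
    genes <- scenario_genes(scenario, grid, emb, n_expressing, rseed)
    expr <- methods::as(do.call(rbind, genes), "CsparseMatrix")
    dimnames(expr) <- list(sprintf("level%02d", seq_along(grid)),
                           sprintf("cell%04d", seq_len(n_cells)))
    prevs <- gene_prevalence(expr)
    prevs <- prevs[prevs > 0]
    background <- fit_background(emb, k_grid = control$k_grid,
                                 n_inits = control$n_inits,
                                 seed = sub_seed(rseed, 2L), reg = control$reg)
    calibration <- calibrate_prevalence_null(
      emb, background, expr, grid_size = control$grid_size,
      n_pseudo = control$n_pseudo, seed = sub_seed(rseed, 3L),
      max_freq = control$max_freq,
      grid_range = c(max(min(prevs) / 1.5, 1 / n_cells),
                     min(max(prevs) * 1.5, control$max_freq)),
      robust = control$robust, k_max_cap = control$k_max_cap, reg = control$reg)
    f0 <- background$per_cell_density

    for (i in seq_along(grid)) {
      w <- genes[[i]]
      if (!any(w > 0)) next
      gseed <- sub_seed(rseed, 4L, i)
      model <- fit_gene_model(emb, w, k_max_cap = control$k_max_cap,
                              seed = gseed, reg = control$reg)
      fg <- wgmm_density(model, emb)
      for (m in methods) {
        p <- NA_real_
        if (m == "locat") {
          prevalence <- mean(w > 0)
          conc <- concentration_pvalue(
            contrast_statistic(w, fg, f0, prevalence), prevalence, calibration)
          if (conc$tested) {
            dep_cfg <- control$depletion
            if (is.null(dep_cfg$neff_cap)) dep_cfg$neff_cap <- n_cells
            dep <- depletion_pvalue(w, fg, f0, dep_cfg)
            comb <- cauchy_combine(conc$p_conc, dep$p_depl)
            p <- smooth_upper_tail(adjusted_score(
              comb$p_loc, sum(w > 0), mean(fg[w > 0] > f0[w > 0]),
              control$alpha_size, control$alpha_sens))
          }
        } else if (m == "lrt") {
          lrt <- likelihood_ratio_test(emb, w, background, gene_model = model,
                                       min_cells = 3L)
          p <- lrt$p_lrt
        } else {
          p <- permutation_pvalue(emb, w, background, calibration,
                                  n_replicates = n_perm_replicates,
                                  seed = gseed, control = control)$p_perm
        }
        rows[[length(rows) + 1L]] <-
          tibble(level = grid[i], replicate = r, method = m, p = p)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$level, .data$method) |>
    dplyr::summarise(median_p = stats::median(.data$p, na.rm = TRUE),
                     frac_significant = mean(.data$p < 0.05, na.rm = TRUE),
                     .groups = "drop")
  crossing <- summary |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(crossing_level = {
      lev <- sort(unique(.data$level))
      med <- .data$median_p[order(.data$level)]
      idx <- which(med > 0.05)
      if (length(idx)) lev[min(idx)] else NA_real_
    }, .groups = "drop")
  structure(list(results = results, summary = summary, crossing = crossing,
                 scenario = scenario, grid = grid,
                 n_replicates = n_replicates, seed = seed),
            class = "locat_power")
}

#' @export
print.locat_power <- function(x, ...) {
  cat(sprintf("Power benchmark '%s': %d levels x %d replicates\n",
              x$scenario, length(x$grid), x$n_replicates))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot a power benchmark
#'
#' Median p-value per level and method on a log scale, with the 0.05
#' threshold dashed.
#'
#' @param object A `"locat_power"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot locat_power
#' @export
autoplot.locat_power <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$level, y = .data$median_p,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$scenario, y = "median p-value") +
    ggplot2::theme_minimal()
}
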