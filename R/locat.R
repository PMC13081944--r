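# Main per-gene localization pipeline.

#' Pipeline configuration
#'
#' Collects every tunable of the localization pipeline with its default.
#'
#' @param max_freq Genes with prevalence above this are reported untested
#'   (default 0.9).
#' @param k_grid Candidate background component counts.
#' @param n_inits Background refits averaged at the selected count.
#' @param k_max_cap Cap on gene-model components.
#' @param reg Covariance ridge for all mixture fits (`NULL` = data-driven).
#' @param grid_size,n_pseudo,robust,grid_range Null-calibration settings, see
#'   [calibrate_prevalence_null()].
#' @param depletion A [depletion_control()] list.
#' @param alpha_size,alpha_sens Penalty strengths, see [adjusted_score()].
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `"locat_control"`.
#' @export
locat_control <- function(max_freq = 0.9, k_grid = 1:10, n_inits = 5L,
                          k_max_cap = 10L, reg = NULL,
                          grid_size = 12L, n_pseudo = 100L, robust = TRUE,
                          grid_range = NULL,
                          depletion = depletion_control(),
                          alpha_size = 0.5, alpha_sens = 0.5, seed = 0L) {
  structure(list(max_freq = max_freq, k_grid = k_grid, n_inits = n_inits,
                 k_max_cap = k_max_cap, reg = reg, grid_size = grid_size,
                 n_pseudo = n_pseudo, robust = robust, grid_range = grid_range,
                 depletion = depletion, alpha_size = alpha_size,
                 alpha_sens = alpha_sens, seed = seed),
            class = "locat_control")
}

# Score one gene against an already-fitted background and calibration.
# Returns a one-row tibble of GeneResult fields.
score_gene <- function(gene_id, w, emb, f0, cal, control, seed) {
  n <- length(w)
  n_expr <- sum(w > 0)
  prevalence <- n_expr / n
  na_row <- tibble(gene_id = gene_id, p_tilde = NA_real_, p_loc = NA_real_,
                   p_conc = NA_real_, p_depl = NA_real_, z_conc = NA_real_,
                   k_components = NA_integer_, bic_like = NA_real_,
                   n_expr = n_expr, prevalence = prevalence, tested = FALSE)
  if (n_expr == 0L || prevalence > control$max_freq) return(na_row)

  model <- fit_gene_model(emb, w, k_max_cap = control$k_max_cap,
                          seed = seed, reg = control$reg)
  fg <- wgmm_density(model, emb)
  z_raw <- contrast_statistic(w, fg, f0, prevalence)
  conc <- concentration_pvalue(z_raw, prevalence, cal)
  if (!conc$tested) return(na_row)

  dep_cfg <- control$depletion
  if (is.null(dep_cfg$neff_cap)) dep_cfg$neff_cap <- n
  dep <- depletion_pvalue(w, fg, f0, dep_cfg)

  comb <- cauchy_combine(conc$p_conc, dep$p_depl)
  frac_dom <- mean(fg[w > 0] > f0[w > 0])
  p_adj <- adjusted_score(comb$p_loc, n_expr, frac_dom,
                          control$alpha_size, control$alpha_sens)
  tibble(gene_id = gene_id,
         p_tilde = smooth_upper_tail(p_adj),
         p_loc = comb$p_loc,
         p_conc = conc$p_conc,
         p_depl = dep$p_depl,
         z_conc = conc$z_adj,
         k_components = model$k_selected,
         bic_like = model$bic,
         n_expr = n_expr, prevalence = prevalence, tested = TRUE)
}

#' Detect localized genes in an embedding
#'
#' Runs the full localization pipeline: fits the background density once,
#' calibrates the concentration null against prevalence-matched pseudo-genes,
#' then scores every expressed gene with prevalence at most `max_freq` — gene
#' density fit, prevalence-adjusted concentration p-value, beta-binomial
#' depletion p-value over the contrast scan, Cauchy combination, sparsity and
#' sensitivity penalties, and upper-tail smoothing. Results for genes above
#' `max_freq` carry `NA` p-values and `tested = FALSE`.
#'
#' @param expr Genes x cells normalized expression matrix (sparse or dense,
#'   with gene/cell dimnames).
#' @param emb Cells x d embedding, rows aligned with the matrix columns.
#' @param control A [locat_control()] configuration.
#' @param background Optional pre-fitted `"background_density"` to reuse.
#' @param calibration Optional pre-computed `"null_calibration"` to reuse.
#'
#' @return An object of class `"locat"`: list with `results` (per-gene
#'   tibble), `background`, `calibration`, `control`. Use [tidy.locat()],
#'   [glance.locat()], [autoplot.locat()] or [write_locat_results()] on it.
#' @export
locat <- function(expr, emb, control = locat_control(),
                  background = NULL, calibration = NULL) {
  expr <- as_expression_matrix(expr)
  emb <- check_embedding(emb, expr)
  seed <- control$seed
  prev <- gene_prevalence(expr)
  if (!any(prev > 0 & prev <= control$max_freq)) {
    stop_locat("no testable genes (all unexpressed or above max_freq)",
               "locat_pipeline_error")
  }
  if (is.null(background)) {
    background <- fit_background(emb, k_grid = control$k_grid,
                                 n_inits = control$n_inits,
                                 seed = sub_seed(seed, 1L), reg = control$reg)
  }
  if (is.null(calibration)) {
    calibration <- calibrate_prevalence_null(
      emb, background, expr,
      grid_size = control$grid_size, n_pseudo = control$n_pseudo,
      seed = sub_seed(seed, 2L), max_freq = control$max_freq,
      grid_range = control$grid_range, robust = control$robust,
      k_max_cap = control$k_max_cap, reg = control$reg)
  }
  f0 <- background$per_cell_density
  tx <- Matrix::t(expr) # cells x genes: fast column access per gene
  results <- dplyr::bind_rows(lapply(seq_len(nrow(expr)), function(g) {
    score_gene(rownames(expr)[g], as.numeric(tx[, g]), emb, f0, calibration,
               control, seed = sub_seed(seed, 3L, g))
  }))
  structure(list(results = results, background = background,
                 calibration = calibration, control = control),
            class = "locat")
}

#' @export
print.locat <- function(x, ...) {
  r <- x$results
  n_sig <- sum(r$p_tilde < 0.05, na.rm = TRUE)
  cat(sprintf("locat: %d genes scored (%d tested), background k0 = %d\n",
              nrow(r), sum(r$tested), x$background$k0))
  cat(sprintf("  %d genes localized at p < 0.05\n", n_sig))
  invisible(x)
}

#' Tidy per-gene localization results
#'
#' @param x A `"locat"` object.
#' @param ... Unused.
#' @return The per-gene tibble, sorted by final p-value (gene id breaks ties).
#' @method tidy locat
#' @export
tidy.locat <- function(x, ...) {
  dplyr::arrange(x$results, .data$p_tilde, .data$gene_id)
}

#' One-row pipeline summary
#'
#' @param x A `"locat"` object.
#' @param alpha Significance threshold used for the localized-gene count.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance locat
#' @export
glance.locat <- function(x, alpha = 0.05, ...) {
  r <- x$results
  tibble(n_genes = nrow(r),
         n_tested = sum(r$tested),
         n_localized = sum(r$p_tilde < alpha, na.rm = TRUE),
         alpha = alpha,
         background_k = x$background$k0,
         median_prevalence = stats::median(r$prevalence))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style overview of a localization run
#'
#' Prevalence against `-log10` final localization p-value, coloured by the
#' significance call at `alpha`.
#'
#' @param object A `"locat"` object.
#' @param alpha Significance threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot locat
#' @export
autoplot.locat <- function(object, alpha = 0.05, ...) {
  r <- dplyr::filter(object$results, .data$tested)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$prevalence,
                                  y = -log10(.data$p_tilde),
                                  colour = .data$p_tilde < alpha)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey40"),
                                 name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "prevalence", y = expression(-log[10]~tilde(p))) +
    ggplot2::theme_minimal()
}

#' Plot one gene's expression on the embedding
#'
#' @param object A `"locat"` object or `NULL`.
#' @param emb Cells x d embedding (first two dimensions plotted).
#' @param weights The gene's expression weights.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_gene_embedding <- function(object = NULL, emb, weights, title = NULL) {
  emb <- check_embedding(emb)
  df <- tibble(x = emb[, 1], y = emb[, 2], w = weights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$w)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient(low = "grey85", high = "#c0392b", name = "weight") +
    ggplot2::labs(x = "dim 1", y = "dim 2", title = title) +
    ggplot2::theme_minimal()
}
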