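# Depletion: beta-binomial lower-tail test over a scan of contrast thresholds.

#' Depletion test configuration
#'
#' @param lambda_grid Strictly increasing contrast thresholds, all `>= 1`;
#'   default 16 geometric points from 1.25 to 100.
#' @param rho_bb Beta-binomial overdispersion in `[0, 1)`; `0` falls back to a
#'   plain binomial tail. Default 0.02.
#' @param neff_scale Multiplicative shrinkage of the effective sample size
#'   before rounding to trials (default 0.6; accounts for dependence between
#'   the fitted densities and between nearby cells).
#' @param neff_cap Upper cap on effective trials; defaults to the number of
#'   cells at test time when `NULL`.
#' @param eps_rel Relative slack in the contrast-consistency admissibility
#'   condition.
#' @param min_beta0 Minimum background mass in the depletion region.
#' @param min_expected_count Minimum `n_eff * beta0`.
#' @param min_deficit Minimum `beta0 - betag`.
#' @param weight_by_expression If `TRUE`, the observed mass weights expressing
#'   cells by expression instead of counting them equally.
#' @return A list of class `"depletion_config"`.
#' @export
depletion_control <- function(lambda_grid = exp(seq(log(1.25), log(100), length.out = 16)),
                              rho_bb = 0.02, neff_scale = 0.6, neff_cap = NULL,
                              eps_rel = 0.05, min_beta0 = 0.05,
                              min_expected_count = 10, min_deficit = 0.01,
                              weight_by_expression = FALSE) {
  stopifnot(all(diff(lambda_grid) > 0), min(lambda_grid) >= 1,
            rho_bb >= 0, rho_bb < 1, neff_scale > 0,
            eps_rel >= 0, min_beta0 >= 0, min_expected_count >= 0, min_deficit >= 0)
  structure(list(lambda_grid = lambda_grid, rho_bb = rho_bb,
                 neff_scale = neff_scale, neff_cap = neff_cap,
                 eps_rel = eps_rel, min_beta0 = min_beta0,
                 min_expected_count = min_expected_count,
                 min_deficit = min_deficit,
                 weight_by_expression = weight_by_expression),
            class = "depletion_config")
}

# Lower tail P(X <= k) of a beta-binomial(n, a, b) by exact log-space summation.
betabinom_lower_tail <- function(k, n, a, b) {
  if (k < 0) return(0)
  k <- min(k, n)
  j <- 0:k
  lt <- lchoose(n, j) + lbeta(j + a, n - j + b) - lbeta(a, b)
  min(1, sum(exp(lt)))
}

#' Depletion tail probability at one contrast threshold
#'
#' Defines the depletion region `Gamma = {c : f_0(x_c) > lambda * f_g(x_c)}`,
#' the model-based background mass `beta0` and the empirical expressing-cell
#' mass `betag` inside it, and evaluates the one-sided lower-tail probability
#' of observing a mass as small as `betag` under a beta-binomial null with
#' `round(min(neff_scale * n_eff, neff_cap))` effective trials, where `n_eff`
#' is Kish's effective sample size of the gene's weights. Admissibility flags
#' whether the contrast carries enough evidence to enter the scan.
#'
#' @param gene_weights Nonnegative expression weights over all cells.
#' @param f_g,f_0 Gene and background densities at each cell.
#' @param lam Contrast threshold `>= 1`.
#' @param cfg A [depletion_control()] configuration.
#' @return A one-row tibble: `lam`, `region_size`, `beta0`, `betag`,
#'   `n_trials`, `k_obs`, `p_tail`, `admissible`.
#' @export
depletion_tail <- function(gene_weights, f_g, f_0, lam, cfg = depletion_control()) {
  stopifnot(lam >= 1)
  n <- length(f_0)
  region <- f_0 > lam * f_g
  expressing <- gene_weights > 0
  beta0 <- if (any(region)) sum(f_0[region]) / sum(f_0) else 0
  betag <- if (!any(region)) 0 else if (cfg$weight_by_expression) {
    sum(gene_weights[region]) / sum(gene_weights)
  } else {
    sum(expressing & region) / sum(expressing)
  }
  neff <- kish_neff(gene_weights)
  cap <- cfg$neff_cap %||% n
  n_trials <- round(min(cfg$neff_scale * neff, cap))
  k_obs <- round(betag * n_trials)
  p_tail <- 1
  if (any(region) && n_trials >= 1 && beta0 > 0 && beta0 < 1) {
    if (cfg$rho_bb == 0) {
      p_tail <- stats::pbinom(k_obs, n_trials, beta0)
    } else {
      conc <- 1 / cfg$rho_bb - 1
      p_tail <- betabinom_lower_tail(k_obs, n_trials, beta0 * conc, (1 - beta0) * conc)
    }
  }
  admissible <- any(region) &&
    beta0 >= cfg$min_beta0 &&
    neff * beta0 >= cfg$min_expected_count &&
    (beta0 - betag) >= cfg$min_deficit &&
    betag < (beta0 / lam) * (1 - cfg$eps_rel)
  tibble(lam = lam, region_size = sum(region), beta0 = beta0, betag = betag,
         n_trials = as.integer(n_trials), k_obs = as.integer(k_obs),
         p_tail = max(p_tail, .Machine$double.xmin), admissible = admissible)
}

#' Depletion p-value over the contrast scan
#'
#' Scans the contrast grid, keeps the admissible subset, takes the minimum
#' tail probability and applies a Sidak-form adjustment for the number of
#' admissible contrasts: `p = 1 - (1 - p_min)^n_admissible`. If no contrast is
#' admissible the depletion p-value is 1. Because tests across contrasts are
#' correlated, the adjustment is an approximate multiplicity correction.
#'
#' @inheritParams depletion_tail
#' @return A list with `p_depl`, `best_contrast` (one-row tibble or `NULL`),
#'   and `scan` (the full per-contrast tibble).
#' @export
depletion_pvalue <- function(gene_weights, f_g, f_0, cfg = depletion_control()) {
  scan <- dplyr::bind_rows(lapply(cfg$lambda_grid, function(l) {
    depletion_tail(gene_weights, f_g, f_0, l, cfg)
  }))
  adm <- dplyr::filter(scan, .data$admissible)
  if (nrow(adm) == 0L) {
    return(list(p_depl = 1, best_contrast = NULL, scan = scan))
  }
  p_min <- min(adm$p_tail)
  n_lambda <- nrow(adm)
  p_depl <- -expm1(n_lambda * log1p(-p_min)) # 1 - (1 - p_min)^n, stable for tiny p_min
  p_depl <- max(p_depl, p_min)
  best <- adm[which.min(adm$p_tail), , drop = FALSE]
  list(p_depl = min(p_depl, 1), best_contrast = best, scan = scan)
}
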