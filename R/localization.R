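# Combining concentration and depletion into the localization score.

#' Cauchy combination of the two component p-values
#'
#' `T = tan((1/2 - p_conc) * pi) + tan((1/2 - p_depl) * pi)` and
#' `p_loc = 1/2 - atan(T) / pi`. The tangent transform makes the combination
#' valid under arbitrary dependence between the component tests. Inputs are
#' clipped into `[1e-15, 1 - 1e-15]` before the transform. The sum form (no
#' 1/2 averaging) is the default; `average = TRUE` gives the conventional
#' equal-weight variant.
#'
#' @param p_conc,p_depl Component p-values in `(0, 1)`.
#' @param average Average the tangents instead of summing them.
#' @return A list with the statistic `T` and the combined `p_loc`.
#' @export
cauchy_combine <- function(p_conc, p_depl, average = FALSE) {
  p1 <- clamp(p_conc, 1e-15, 1 - 1e-15)
  p2 <- clamp(p_depl, 1e-15, 1 - 1e-15)
  T_stat <- tan((0.5 - p1) * pi) + tan((0.5 - p2) * pi)
  if (average) T_stat <- T_stat / 2
  list(T = T_stat, p_loc = 0.5 - atan(T_stat) / pi)
}

#' Penalty-adjusted localization score
#'
#' Applies two conservative penalties to the Cauchy-combined value: a sparsity
#' penalty `h_size = 1 - exp(-1 / (n_expr + 1))` (large only for genes with
#' very few expressing cells, where density fits are unstable) and a
#' sensitivity penalty `h_sens = 1 - frac_dominated` (large when the fitted
#' gene density fails to dominate the background at most expressing cells).
#' The adjusted score
#' `p = 1 - (1 - p_loc) * (1 - a_size * h_size) * (1 - a_sens * h_sens)`
#' always satisfies `p >= p_loc`.
#'
#' @param p_loc Cauchy-combined p-value.
#' @param n_expr Number of expressing cells.
#' @param frac_dominated Fraction of expressing cells where `f_g > f_0`.
#' @param alpha_size,alpha_sens Penalty strengths in `[0, 1]`.
#' @return The adjusted score, clipped into `(0, 1)`.
#' @export
adjusted_score <- function(p_loc, n_expr, frac_dominated,
                           alpha_size = 0.5, alpha_sens = 0.5) {
  stopifnot(alpha_size >= 0, alpha_size <= 1, alpha_sens >= 0, alpha_sens <= 1,
            n_expr >= 0, frac_dominated >= 0, frac_dominated <= 1)
  h_size <- 1 - exp(-1 / (n_expr + 1))
  h_sens <- 1 - frac_dominated
  p <- 1 - (1 - p_loc) * (1 - alpha_size * h_size) * (1 - alpha_sens * h_sens)
  clamp(p, .Machine$double.xmin, 1 - .Machine$double.eps)
}

#' Monotone upper-tail smoothing
#'
#' Identity below 0.99; above, values are remapped by
#' `1 - 0.01 / (1 + 100 * (p - 0.99) + 1e4 * (p - 0.99)^2)`, a strictly
#' increasing, continuous map that keeps the output below 1 and spreads apart
#' scores that would otherwise collapse onto the upper boundary. Ranks are
#' preserved everywhere.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Smoothed values.
#' @export
smooth_upper_tail <- function(p) {
  out <- p
  hi <- p > 0.99
  d <- p[hi] - 0.99
  out[hi] <- 1 - 0.01 / (1 + 100 * d + 1e4 * d^2)
  out
}

#' Combine replicate localization p-values
#'
#' Geometric mean of per-replicate p-values; compared to the significance
#' threshold to call localization at the replicate-group level.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return A single combined value.
#' @export
combine_replicates <- function(p_values) {
  if (!length(p_values)) stop_locat("no p-values to combine", "locat_validation_error")
  if (any(p_values <= 0 | p_values > 1)) {
    stop_locat("replicate p-values must lie in (0, 1]", "locat_validation_error")
  }
  exp(mean(log(p_values)))
}

#' Differential localization between two conditions
#'
#' A gene is differentially localized when significantly localized (final
#' p-value below `alpha`) in one condition but not in the other; genes
#' untested in a condition count as not localized there.
#'
#' @param results_a,results_b Per-gene result tibbles with `gene_id` and
#'   `p_tilde` columns.
#' @param alpha Significance threshold in `(0, 1)`.
#' @return A list of character vectors: `only_a`, `only_b`, `shared`.
#' @export
differential_localization <- function(results_a, results_b, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig <- function(res) {
    res <- as_tibble(res)
    res$gene_id[!is.na(res$p_tilde) & res$p_tilde < alpha]
  }
  sa <- sig(results_a); sb <- sig(results_b)
  list(only_a = setdiff(sa, sb),
       only_b = setdiff(sb, sa),
       shared = intersect(sa, sb))
}
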