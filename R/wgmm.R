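#' Kish effective sample size
#'
#' The equivalent number of equally weighted observations carried by a
#' nonnegative weight vector: `(sum(w))^2 / sum(w^2)`. Lies between 1 and the
#' number of positive weights, with equality at the extremes for a single
#' positive weight and for uniform weights respectively.
#'
#' @param weights Nonnegative numeric vector with at least one positive entry.
#' @return A single number.
#' @export
kish_neff <- function(weights) {
  if (any(weights < 0) || !all(is.finite(weights))) {
    stop_locat("weights must be finite and nonnegative", "locat_validation_error")
  }
  s <- sum(weights)
  if (s <= 0) stop_locat("all weights are zero", "locat_validation_error")
  s^2 / sum(weights^2)
}

# Log-density of one Gaussian component via Cholesky; x is n x d.
mvn_logdensity <- function(x, mean, cov) {
  d <- ncol(x)
  ch <- chol(cov)
  centered <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

default_reg <- function(points) {
  v <- apply(points, 2L, stats::var)
  max(1e-6 * stats::median(v), 1e-12)
}

#' Fit a weighted Gaussian mixture model
#'
#' Expectation-maximisation for a Gaussian mixture under per-observation
#' weights (normalized internally to sum to one). The weighted log-likelihood
#' `sum(w_c * log f(x_c))` is non-decreasing over iterations; full covariance
#' matrices are regularized by adding `reg` to their diagonals.
#'
#' @param points Numeric matrix, n observations x d dimensions.
#' @param weights Nonnegative weights of length n; at least `k` must be
#'   positive.
#' @param k Number of mixture components.
#' @param seed Integer seed for the initialisation.
#' @param reg Covariance ridge; defaults to `1e-6` times the median coordinate
#'   variance.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change below
#'   `tol` or `max_iter` iterations.
#'
#' @return An object of class `"wgmm"` with elements `k`, `means` (k x d),
#'   `covariances` (list of d x d), `mix_weights`, `loglik` (weighted, final),
#'   `loglik_trace`, `n_iter`, `reg`.
#' @export
fit_wgmm <- function(points, weights = NULL, k = 1L, seed = 0L,
                     reg = NULL, max_iter = 200L, tol = 1e-6) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    stop_locat("points must be finite", "locat_validation_error")
  }
  n <- nrow(points); d <- ncol(points)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) {
    stop_locat("weights length must match number of points", "locat_validation_error")
  }
  pos <- which(weights > 0)
  if (length(pos) < k) {
    stop_locat(sprintf("k = %d exceeds the %d positively weighted points", k, length(pos)),
               "locat_fit_error")
  }
  w <- weights / sum(weights)
  if (is.null(reg)) reg <- default_reg(points[pos, , drop = FALSE])

  # zero-weight observations contribute nothing to the weighted likelihood:
  # drop them so EM cost scales with the support, not the dataset
  if (length(pos) < n) {
    points <- points[pos, , drop = FALSE]
    w <- w[pos]
    n <- length(pos)
    pos <- seq_len(n)
  }

  # init: distinct points drawn with probability proportional to weight
  init_idx <- with_seed(seed, {
    if (length(pos) == k) pos else sample(pos, k, prob = w[pos])
  })
  means <- points[init_idx, , drop = FALSE]
  mu0 <- colSums(points * w)
  centered0 <- sweep(points, 2L, mu0)
  cov0 <- crossprod(sqrt(w) * centered0) + diag(reg, d)
  covs <- rep(list(cov0), k)
  mix <- rep(1 / k, k)

  covs_cube <- array(unlist(covs), dim = c(d, d, k))
  fit <- wgmm_em_cpp(points, w, means, covs_cube, mix, reg, max_iter, tol)

  structure(list(
    k = as.integer(k), d = as.integer(d),
    means = fit$means,
    covariances = lapply(seq_len(k), function(j) matrix(fit$covs[, , j], d, d)),
    mix_weights = as.numeric(fit$mix),
    loglik = fit$loglik_trace[length(fit$loglik_trace)],
    loglik_trace = as.numeric(fit$loglik_trace),
    n_iter = fit$n_iter, reg = reg
  ), class = "wgmm")
}

#' Evaluate a fitted mixture density
#'
#' @param model A `"wgmm"` object.
#' @param points Matrix of evaluation positions (n x d).
#' @param log Return log-density?
#' @param floor Lower floor applied to the (non-log) density to keep
#'   downstream ratios finite.
#' @return Numeric vector of densities.
#' @export
wgmm_density <- function(model, points, log = FALSE, floor = 1e-300) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  covs <- array(unlist(model$covariances), dim = c(model$d, model$d, model$k))
  lf <- as.numeric(wgmm_logdensity_cpp(points, model$means, covs, model$mix_weights))
  if (log) return(pmax(lf, log(floor)))
  pmax(exp(lf), floor)
}

wgmm_free_params <- function(k, d) {
  (k - 1) + k * d + k * d * (d + 1) / 2
}

#' BIC-style model selection score for a weighted mixture
#'
#' `-2 * n_eff * sum(w * log f(x)) + n_par * log(n_eff)` where the effective
#' sample size `n_eff` is Kish's measure of the weight vector. With uniform
#' weights this reduces to the ordinary BIC; unequal weights shrink the
#' effective evidence and so favour simpler models. Lower is better.
#'
#' @param model A `"wgmm"` object.
#' @param points Matrix the model is evaluated on.
#' @param weights Nonnegative weights (normalized internally).
#' @return A single number.
#' @export
wgmm_bic <- function(model, points, weights = NULL) {
  points <- as.matrix(points)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  w <- weights / sum(weights)
  neff <- kish_neff(weights)
  ll <- sum(w * wgmm_density(model, points, log = TRUE))
  -2 * neff * ll + wgmm_free_params(model$k, ncol(points)) * log(neff)
}

#' @export
print.wgmm <- function(x, ...) {
  cat(sprintf("Weighted Gaussian mixture: k = %d, d = %d, loglik = %.4f (%d EM iterations)\n",
              x$k, x$d, x$loglik, x$n_iter))
  invisible(x)
}
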