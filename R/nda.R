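# Neighborhood differential abundance: multiscale signed enrichment.

# Exact k-nearest-neighbour indices (Euclidean), query cell excluded,
# computed in chunks to bound memory. Results are chunking-invariant.
knn_indices <- function(emb, k, chunk_size = 1024L) {
  n <- nrow(emb)
  out <- matrix(0L, n, k)
  sq <- rowSums(emb^2)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    d2 <- outer(sq[idx], sq) - 2 * tcrossprod(emb[idx, , drop = FALSE], emb)
    d2[cbind(seq_along(idx), idx)] <- Inf # exclude self
    out[idx, ] <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Multiscale neighborhood enrichment scores
#'
#' For each cell and each neighbourhood size `k`, computes the local group
#' fraction over the `k` nearest neighbours (query cell excluded) and maps it
#' through the Bayes-rule-derived signed transform
#' `s = 2 * (qhat/q1) / ((qhat/q1) + ((1-qhat)/(1-q1))) - 1`,
#' which is 0 when the local fraction matches the global prevalence `q1` and
#' saturates at +/-1. Swapping the group labels negates every score exactly.
#'
#' @param emb Cells x d embedding.
#' @param labels Per-cell group membership: hard `{0,1}` or soft `[0,1]`.
#' @param scales Neighbourhood sizes (default 15, 40, 75).
#' @return Matrix of scores, cells x scales, with `q1` as an attribute.
#' @export
multiscale_scores <- function(emb, labels, scales = c(15L, 40L, 75L)) {
  emb <- check_embedding(emb)
  n <- nrow(emb)
  if (length(labels) != n) stop_locat("labels length must match cells", "locat_validation_error")
  if (any(labels < 0 | labels > 1)) {
    stop_locat("labels must lie in [0, 1]", "locat_validation_error")
  }
  if (n < max(scales) + 1L) {
    stop_locat("need at least max(scales) + 1 cells", "locat_validation_error")
  }
  q1 <- mean(labels)
  if (q1 <= 0 || q1 >= 1) {
    stop_locat("labels contain a single group; enrichment undefined", "locat_degenerate_error")
  }
  nn <- knn_indices(emb, max(scales))
  lab_nn <- matrix(labels[nn], nrow = n)
  S <- vapply(scales, function(k) {
    qhat <- rowMeans(lab_nn[, seq_len(k), drop = FALSE])
    r1 <- qhat / q1
    r0 <- (1 - qhat) / (1 - q1)
    2 * r1 / (r1 + r0) - 1
  }, numeric(n))
  S <- matrix(S, nrow = n, dimnames = list(NULL, paste0("s_k", scales)))
  attr(S, "q1") <- q1
  attr(S, "scales") <- scales
  S
}

#' Aggregate multiscale scores into a final nDA score
#'
#' Fits a ridge-regularized logistic classifier of group membership on the
#' multiscale score matrix (balanced class weights by default) and rescales
#' the fitted posterior probabilities linearly to `[-1, 1]`. Regularization
#' keeps the fit defined under perfect separation.
#'
#' @param S Score matrix from [multiscale_scores()] (>= 2 columns).
#' @param labels Per-cell group membership.
#' @param class_weights `"balanced"` (default) or `"none"`.
#' @param C Inverse regularization strength (default 1).
#' @return An object of class `"nda_result"`: tibble with the per-scale
#'   scores and the final `score` column, plus `q1`.
#' @export
aggregate_nda <- function(S, labels, class_weights = c("balanced", "none"), C = 1) {
  class_weights <- match.arg(class_weights)
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) < 2L) stop_locat("S needs at least two scales", "locat_validation_error")
  if (length(labels) != n) stop_locat("labels length must match S rows", "locat_validation_error")
  y <- as.integer(labels > 0.5)
  w <- rep(1, n)
  if (class_weights == "balanced") {
    tab <- table(factor(y, levels = c(0, 1)))
    if (any(tab == 0)) stop_locat("single-class labels", "locat_degenerate_error")
    w <- n / (2 * as.numeric(tab[as.character(y)]))
  }
  if (all(apply(S, 2L, stats::sd) < 1e-12)) {
    # no information in the scores: intercept-only fit, i.e. the (weighted)
    # global class rate
    prob <- rep(sum(w * y) / sum(w), n)
    fit <- NULL
  } else {
    fit <- glmnet::glmnet(S, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = 0, lambda = 1 / (n * C), weights = w,
                          standardize = FALSE)
    prob <- as.numeric(stats::predict(fit, newx = S, type = "response"))
  }
  res <- as_tibble(S)
  res$score <- 2 * prob - 1
  structure(list(scores = res, q1 = attr(S, "q1") %||% mean(labels),
                 fit = fit), class = "nda_result")
}

#' Neighborhood differential abundance, end to end
#'
#' Convenience wrapper: [multiscale_scores()] then [aggregate_nda()].
#'
#' @inheritParams multiscale_scores
#' @inheritParams aggregate_nda
#' @return An `"nda_result"`.
#' @export
nda <- function(emb, labels, scales = c(15L, 40L, 75L),
                class_weights = "balanced", C = 1) {
  S <- multiscale_scores(emb, labels, scales)
  aggregate_nda(S, labels, class_weights = class_weights, C = C)
}

#' @export
print.nda_result <- function(x, ...) {
  cat(sprintf("nDA result: %d cells, global prevalence q1 = %.3f\n",
              nrow(x$scores), x$q1))
  cat(sprintf("  mean |score| = %.3f\n", mean(abs(x$scores$score))))
  invisible(x)
}

#' Plot nDA scores on an embedding
#'
#' @param object An `"nda_result"`.
#' @param emb Cells x d embedding (first two dimensions shown).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nda_result
#' @export
autoplot.nda_result <- function(object, emb, ...) {
  emb <- check_embedding(emb)
  df <- tibble(x = emb[, 1], y = emb[, 2], score = object$scores$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey90",
                                    high = "#b2182b", limits = c(-1, 1),
                                    name = "nDA") +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}
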