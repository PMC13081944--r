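# Internal helpers shared across the package.

# Derive a reproducible child seed from a master seed. Kept below .Machine's
# 32-bit integer ceiling so set.seed() never overflows.
sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p)) %% 2147483647
  as.integer(s)
}

# Evaluate `code` under a local RNG state seeded with `seed`, leaving the
# caller's RNG untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_locat <- function(msg, class) {
  rlang::abort(msg, class = c(class, "locat_error"))
}

# Coerce expression input to a sparse dgCMatrix with dimnames, validating the
# ExpressionMatrix invariants (nonnegative, unique gene/cell ids).
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  m <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) {
    stop_locat("expression values must be nonnegative", "locat_validation_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_locat("expression matrix must carry gene (row) and cell (column) identifiers",
               "locat_validation_error")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_locat("duplicate gene or cell identifiers in expression matrix",
               "locat_validation_error")
  }
  m
}

# Validate an embedding (cells x d) against an expression matrix's cell order.
check_embedding <- function(emb, expr = NULL) {
  emb <- as.matrix(emb)
  storage.mode(emb) <- "double"
  if (!all(is.finite(emb))) {
    stop_locat("embedding coordinates must all be finite", "locat_validation_error")
  }
  if (ncol(emb) < 1L) stop_locat("embedding needs d >= 1", "locat_validation_error")
  if (!is.null(expr)) {
    if (nrow(emb) != ncol(expr)) {
      stop_locat(sprintf(
        "embedding has %d rows but expression matrix has %d cells",
        nrow(emb), ncol(expr)), "locat_validation_error")
    }
    if (!is.null(rownames(emb)) &&
        !identical(rownames(emb), colnames(expr))) {
      stop_locat("embedding row names do not match expression cell identifiers (order matters)",
                 "locat_validation_error")
    }
  }
  emb
}
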