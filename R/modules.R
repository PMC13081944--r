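# Co-expression module discovery over a hypergeometric gene graph.

#' Binarize expression and build the co-occurrence gene graph
#'
#' Binarizes the expression matrix at threshold `t` (`b = 1` iff `w > t`) and,
#' for each unordered gene pair, tests whether the overlap of expressing-cell
#' sets exceeds the hypergeometric expectation (upper tail,
#' `P(overlap >= observed)`). Pairs with p-value at most `alpha` become edges
#' of an unweighted gene graph. No multiple-testing correction is applied by
#' default (edges are screened at raw `alpha`); `adjust = "BH"` switches to
#' Benjamini-Hochberg-adjusted edge p-values.
#'
#' @param expr Genes x cells expression matrix.
#' @param gene_subset Character vector of gene identifiers to include.
#' @param t Binarization threshold (default 0).
#' @param alpha Edge significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `"gene_graph"`: `graph` (igraph, vertices named by
#'   gene), `edges` (tibble with `gene1`, `gene2`, `overlap`, `p_hyper`),
#'   `alpha`, `t`.
#' @export
coexpression_graph <- function(expr, gene_subset = rownames(expr),
                               t = 0, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  expr <- as_expression_matrix(expr)
  stopifnot(length(gene_subset) >= 1, t >= 0)
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing)) {
    stop_locat(paste0("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", ")),
               "locat_lookup_error")
  }
  b <- expr[gene_subset, , drop = FALSE] > t
  b <- as(b, "lMatrix")
  n <- ncol(b)
  support <- Matrix::rowSums(b)
  overlap <- as.matrix(Matrix::tcrossprod(b * 1))
  m <- length(gene_subset)
  pairs <- which(upper.tri(overlap), arr.ind = TRUE)
  ov <- overlap[pairs]
  s1 <- support[pairs[, 1]]; s2 <- support[pairs[, 2]]
  # upper tail P(X >= ov) with X ~ Hypergeometric(s1 white, n - s1 black, s2 draws)
  p <- stats::phyper(ov - 1, s1, n - s1, s2, lower.tail = FALSE)
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  edges <- tibble(gene1 = gene_subset[pairs[, 1]],
                  gene2 = gene_subset[pairs[, 2]],
                  overlap = as.integer(ov), p_hyper = p,
                  significant = p_eff <= alpha)
  g <- igraph::graph_from_data_frame(
    edges[edges$significant, c("gene1", "gene2")],
    directed = FALSE,
    vertices = data.frame(name = gene_subset))
  structure(list(graph = g, edges = edges, alpha = alpha, t = t),
            class = "gene_graph")
}

#' Detect gene modules by Louvain community detection
#'
#' Partitions the binary co-occurrence graph with Louvain community detection
#' (resolution 1, unweighted edges), drops communities smaller than
#' `min_module_size`, and returns modules sorted by size descending.
#'
#' @param graph A `"gene_graph"` from [coexpression_graph()].
#' @param min_module_size Minimum genes per retained module (default 5).
#' @param seed Seed for the Louvain heuristic.
#' @return A list of character vectors (gene identifiers), largest first;
#'   empty list (with a warning) for an edgeless graph.
#' @export
detect_modules <- function(graph, min_module_size = 5L, seed = 0L) {
  g <- graph$graph
  if (igraph::ecount(g) == 0L) {
    rlang::warn("gene graph has no edges; no modules")
    return(list())
  }
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = 1))
  groups <- igraph::communities(comm)
  groups <- Filter(function(m) length(m) >= min_module_size, groups)
  groups <- groups[order(-vapply(groups, length, numeric(1)))]
  unname(lapply(groups, as.character))
}

#' Module membership as a tibble
#'
#' @param modules List of gene modules from [detect_modules()].
#' @return Tibble with `module` (integer) and `gene_id`.
#' @export
module_membership <- function(modules) {
  if (!length(modules)) return(tibble(module = integer(), gene_id = character()))
  dplyr::bind_rows(purrr::imap(modules, function(genes, i) {
    tibble(module = as.integer(i), gene_id = genes)
  }))
}
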