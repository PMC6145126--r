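# Pearson coexpression networks: all gene (or family) pairs whose
# correlation magnitude strictly exceeds a threshold at a two-sided
# significance level.

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t reference under bivariate-normal independence:
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} with \code{n - 2} degrees of
#' freedom; \code{|r| = 1} gives p = 0.
#'
#' @param r Correlation value(s) in [-1, 1].
#' @param n Number of paired samples (>= 3).
#' @return p-value(s) in [0, 1].
#' @export
pccPvalue <- function(r, n) {
  if (any(n < 3)) stop("'n' must be >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("'r' outside [-1, 1]", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  one <- abs(r) >= 1
  p[one] <- 0
  ok <- !is.na(r) & !one
  t <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(t), df = n - 2)
  p
}

#' Build a thresholded Pearson coexpression network
#'
#' Computes all pairwise Pearson correlations between the rows of an
#' expression matrix and keeps the pairs with \code{|r|} strictly greater
#' than \code{min_abs_pcc} and p strictly below \code{alpha}.  Constant
#' rows (undefined correlation) are dropped and reported.  Setting
#' \code{min_abs_pcc = 0.9} reproduces the stricter variant used for
#' duplicate-gene networks.
#'
#' @param mat Rows = genes or families, columns = samples (>= 3).
#' @param min_abs_pcc Strict lower bound on \code{|r|} (default 0.8).
#' @param alpha Strict upper bound on the p-value (default 0.01).
#' @param adjust Optional multiple-testing correction passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}, matching the
#'   plain per-pair test).
#' @return A \code{\linkS4class{CoexpressionNetwork}}.
#' @export
buildCoexpressionNetwork <- function(mat, min_abs_pcc = 0.8, alpha = 0.01,
                                     adjust = "none") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(mat, 1, sd)
  dropped <- rownames(mat)[v == 0]
  x <- mat[v > 0, , drop = FALSE]
  n <- ncol(x)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(x) >= 2) {
    C <- cor(t(x))
    idx <- which(upper.tri(C), arr.ind = TRUE)
    r <- C[idx]
    p <- pccPvalue(r, n)
    if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
    keep <- abs(r) > min_abs_pcc & p < alpha
    if (any(keep)) {
      a <- rownames(x)[idx[keep, 1]]
      b <- rownames(x)[idx[keep, 2]]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      edges <- data.frame(node_a = a, node_b = b, r = r[keep], p = p[keep],
                          sign = ifelse(r[keep] > 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  new("CoexpressionNetwork", edges = edges,
      params = list(min_abs_pcc = min_abs_pcc, alpha = alpha, n_samples = n),
      dropped = as.character(dropped))
}

#' Node degrees and connected components of a coexpression network
#'
#' @param x A \code{\linkS4class{CoexpressionNetwork}} or an edge
#'   data.frame with \code{node_a}, \code{node_b}.
#' @return List: \code{degree} (named, nodes with >= 1 edge only),
#'   \code{components} (data.frame \code{node}, \code{component}),
#'   \code{component_sizes}, \code{n_nodes}, \code{n_edges},
#'   \code{n_components}.
#' @export
degreeAndComponents <- function(x) {
  edges <- if (is(x, "CoexpressionNetwork")) networkEdges(x) else x
  if (nrow(edges) == 0L)
    return(list(degree = integer(0),
                components = data.frame(node = character(0),
                                        component = integer(0)),
                component_sizes = integer(0),
                n_nodes = 0L, n_edges = 0L, n_components = 0L))
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  components <- data.frame(node = names(comp$membership),
                           component = as.integer(comp$membership),
                           stringsAsFactors = FALSE)
  list(degree = deg,
       components = components[order(components$component,
                                     components$node), , drop = FALSE],
       component_sizes = as.integer(comp$csize),
       n_nodes = igraph::vcount(g),
       n_edges = nrow(edges),
       n_components = comp$no)
}
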