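# FPKM matrix filtering, transformation, family aggregation, and k-means
# clustering under Pearson correlation distance (d = 1 - r).

#' Filter lowly expressed genes
#'
#' A gene is filtered iff every sample value is strictly below
#' \code{threshold} (a gene reaching the threshold in even one sample is
#' retained).  The retained/filtered sets partition the input exactly.
#'
#' @param mat Numeric matrix, genes x samples (rownames = gene ids).
#' @param threshold Positive FPKM cutoff (default 10).
#' @return List: \code{retained} (sub-matrix), \code{filtered} (character
#'   vector of filtered gene ids).
#' @export
filterLowExpression <- function(mat, threshold = 10) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  mat <- as.matrix(mat)
  low <- apply(mat, 1, function(x) all(x < threshold))
  list(retained = mat[!low, , drop = FALSE],
       filtered = rownames(mat)[low])
}

#' log2(FPKM + 1) transform
#'
#' @param mat Non-negative numeric matrix.
#' @return Matrix of \code{log2(mat + 1)} (zero maps to zero).
#' @export
logTransform <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative expression values", call. = FALSE)
  log2(mat + 1)
}

#' Family-averaged expression
#'
#' Arithmetic mean of the member-gene profiles of each family, per sample.
#' Families with no member present in the matrix are omitted.
#'
#' @param mat Genes x samples matrix.
#' @param families Named character vector gene id -> family, or a
#'   \code{\linkS4class{KinaseCatalog}}.
#' @return Families x samples matrix.
#' @export
familyMeanExpression <- function(mat, families) {
  if (is(families, "KinaseCatalog")) {
    rec <- catalogRecords(families)
    families <- setNames(rec$family, rec$gene_id)
  }
  mat <- as.matrix(mat)
  fam <- families[match(rownames(mat), names(families))]
  keep <- !is.na(fam)
  mat <- mat[keep, , drop = FALSE]
  fam <- fam[keep]
  if (nrow(mat) == 0L)
    return(matrix(numeric(0), 0, ncol(mat),
                  dimnames = list(NULL, colnames(mat))))
  out <- rowsum(mat, fam) / as.vector(table(fam)[sort(unique(fam))])
  out[order(rownames(out)), , drop = FALSE]
}

# Pearson distance of each row of x to each centroid row: 1 - r, with
# distance 2 (maximal) to a zero-variance centroid.
.pearsonDist <- function(x, centroids) {
  csd <- apply(centroids, 1, sd)
  d <- matrix(2, nrow(x), nrow(centroids))
  ok <- csd > 0
  if (any(ok))
    d[, ok] <- 1 - cor(t(x), t(centroids[ok, , drop = FALSE]))
  d
}

.kmeansOnce <- function(x, k, max_iter) {
  n <- nrow(x)
  centroids <- x[sample.int(n, k), , drop = FALSE]
  assign <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d <- .pearsonDist(x, centroids)
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty) == 0L) break
      cur <- d[cbind(seq_len(n), new_assign)]
      far <- which.max(cur)
      new_assign[far] <- empty[1]
      d[far, ] <- Inf
      d[far, empty[1]] <- 0
    }
    if (all(new_assign == assign)) break
    assign <- new_assign
    centroids <- rowsum(x, assign) / as.vector(table(assign))
  }
  d <- .pearsonDist(x, centroids)
  objective <- sum(d[cbind(seq_len(n), assign)])
  list(cluster = assign, centroids = centroids, objective = objective)
}

#' k-means clustering with Pearson correlation distance
#'
#' Partitions gene expression profiles into \code{k} clusters minimizing
#' the summed Pearson distance \code{1 - cor(x, centroid)} to the cluster
#' centroids (arithmetic means of the member profiles).  Runs
#' \code{n_restarts} random initializations and keeps the run with the
#' lowest objective; deterministic for a given \code{seed}.  Zero-variance
#' rows (Pearson distance undefined) are removed first and reported.
#'
#' @param mat Genes x samples numeric matrix.
#' @param k Number of clusters (default 10).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter Maximum iterations per restart (default 100).
#' @return List: \code{cluster} (named integer vector in 1..k),
#'   \code{centroids} (k x samples), \code{objective},
#'   \code{restart_objectives}, and \code{dropped} (zero-variance gene
#'   ids).
#' @export
kmeansPearson <- function(mat, k = 10, n_restarts = 10, seed = 1,
                          max_iter = 100) {
  mat <- as.matrix(mat)
  v <- apply(mat, 1, sd)
  dropped <- rownames(mat)[v == 0]
  x <- mat[v > 0, , drop = FALSE]
  if (!is.numeric(k) || k <= 0 || k != floor(k))
    stop("'k' must be a positive integer", call. = FALSE)
  if (k > nrow(x))
    stop("'k' exceeds the number of usable rows", call. = FALSE)
  withSeed(seed, {
    runs <- lapply(seq_len(n_restarts), function(i) .kmeansOnce(x, k, max_iter))
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    best <- runs[[which.min(objs)]]
    list(cluster = setNames(best$cluster, rownames(x)),
         centroids = best$centroids,
         objective = best$objective,
         restart_objectives = objs,
         dropped = dropped)
  })
}
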