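# Simulated FPKM matrices with planted clusters and lowly expressed genes.

#' Default tissue panel emulated by the expression simulator
#' @return Character vector of 14 tissue labels.
#' @export
defaultTissuePanel <- function() {
  c("root", "stem", "leaf", "flower", "fruit_S1", "fruit_S2", "fruit_S3",
    "fruit_S4", "fruit_S5", "seed", "sepal", "petal", "ovule", "calyx")
}

#' Default diurnal sample panel (two leaf sections x 12 time points)
#' @return Character vector of 24 labels (\code{greenTip_00h} ...
#'   \code{whiteBase_22h}), 2-h resolution over 24 h.
#' @export
defaultDiurnalPanel <- function() {
  tp <- sprintf("%02dh", seq(0, 22, by = 2))
  c(paste0("greenTip_", tp), paste0("whiteBase_", tp))
}

#' Well-separated cluster mean profiles
#'
#' Builds \code{k} smooth bump-shaped mean FPKM profiles with distinct peak
#' positions, ranging from a low baseline to a high peak, so the planted
#' clusters are well separated under Pearson correlation distance.
#'
#' @param k Number of clusters.
#' @param samples Character vector of sample labels.
#' @param baseline,peak Baseline and peak FPKM of each profile.
#' @return k x length(samples) matrix.
#' @export
defaultClusterProfiles <- function(k, samples, baseline = 15, peak = 120) {
  p <- length(samples)
  if (k < 1 || p < 2) stop("need k >= 1 and >= 2 samples", call. = FALSE)
  centers <- seq(1, p, length.out = k)
  width <- max(p / (2 * k), 0.75)
  prof <- t(vapply(centers, function(c0) {
    baseline + (peak - baseline) * exp(-((seq_len(p) - c0)^2) / (2 * width^2))
  }, numeric(p)))
  dimnames(prof) <- list(paste0("cluster", seq_len(k)), samples)
  prof
}

#' Configuration for a simulated expression matrix
#'
#' Defaults emulate a developmental panel: 758 genes over 14 tissues with
#' ten planted clusters and roughly a third of the genes lowly expressed,
#' mirroring a typical plant-kinome FPKM table.
#'
#' @param n_genes Total gene count.
#' @param sample_labels Ordered sample labels.
#' @param n_clusters Number of planted clusters.
#' @param cluster_profiles Optional n_clusters x samples matrix of mean
#'   FPKM profiles (default \code{\link{defaultClusterProfiles}}).
#' @param cluster_sizes Optional expressed-gene counts per cluster; must
#'   sum to the expressed-gene count (default: near-equal split).
#' @param noise_sd Gaussian noise SD added to each expressed value.
#' @param frac_low_expressed Fraction of genes planted with all values
#'   below 10.
#' @param seed Integer seed.
#' @return A validated list of class \code{ExpressionSimConfig}.
#' @export
simExpressionConfig <- function(n_genes = 758,
                                sample_labels = defaultTissuePanel(),
                                n_clusters = 10,
                                cluster_profiles = NULL,
                                cluster_sizes = NULL,
                                noise_sd = 5,
                                frac_low_expressed = 0.35,
                                seed = 1) {
  n_genes <- .assertCount(n_genes, "n_genes", min = 1L)
  n_clusters <- .assertCount(n_clusters, "n_clusters", min = 1L)
  frac_low_expressed <- .assertFraction(frac_low_expressed,
                                        "frac_low_expressed")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.null(cluster_profiles))
    cluster_profiles <- defaultClusterProfiles(n_clusters, sample_labels)
  cluster_profiles <- as.matrix(cluster_profiles)
  if (nrow(cluster_profiles) != n_clusters ||
      ncol(cluster_profiles) != length(sample_labels))
    stop("'cluster_profiles' must be n_clusters x length(sample_labels)",
         call. = FALSE)
  if (any(apply(cluster_profiles, 1, max) < 10))
    stop("each cluster profile must reach FPKM >= 10 somewhere, otherwise ",
         "its members cannot survive the low-expression filter",
         call. = FALSE)
  n_low <- round(frac_low_expressed * n_genes)
  n_expr <- n_genes - n_low
  if (is.null(cluster_sizes)) {
    base <- n_expr %/% n_clusters
    cluster_sizes <- rep(base, n_clusters)
    extra <- n_expr - sum(cluster_sizes)
    if (extra > 0) cluster_sizes[seq_len(extra)] <- base + 1L
  }
  if (sum(cluster_sizes) != n_expr)
    stop("'cluster_sizes' must sum to the expressed-gene count (",
         n_expr, ")", call. = FALSE)
  if (n_expr > 0 && n_expr < n_clusters)
    stop("fewer expressed genes than clusters", call. = FALSE)
  structure(list(n_genes = n_genes, sample_labels = sample_labels,
                 n_clusters = n_clusters,
                 cluster_profiles = cluster_profiles,
                 cluster_sizes = as.integer(cluster_sizes),
                 noise_sd = noise_sd, n_low = as.integer(n_low),
                 frac_low_expressed = frac_low_expressed, seed = seed),
            class = "ExpressionSimConfig")
}

#' Simulate an FPKM matrix with planted clusters
#'
#' Lowly expressed genes get uniform values in [0, 10) (so the downstream
#' filter removes exactly those genes); each expressed gene is its cluster
#' mean profile plus Gaussian noise, truncated at zero, re-drawn in the
#' rare case that noise pushes every value below 10 so the planted
#' expressed/low partition is exact by construction.
#'
#' @param config An \code{\link{simExpressionConfig}}.
#' @return List: \code{fpkm} (genes x samples matrix), \code{truth}
#'   (data.frame \code{gene_id}, \code{cluster}; cluster \code{NA} for
#'   lowly expressed genes).
#' @export
simExpressionData <- function(config) {
  stopifnot(inherits(config, "ExpressionSimConfig"))
  withSeed(config$seed, {
    p <- length(config$sample_labels)
    n <- config$n_genes
    ids <- sprintf("gene%04d", seq_len(n))
    cluster <- rep(NA_integer_, n)
    if (sum(config$cluster_sizes) > 0)
      cluster[seq_len(sum(config$cluster_sizes))] <-
        rep(seq_len(config$n_clusters), times = config$cluster_sizes)
    # shuffle gene order so cluster membership is not positional
    ord <- sample.int(n)
    cluster <- cluster[ord]
    fpkm <- matrix(0, n, p, dimnames = list(ids, config$sample_labels))
    for (i in seq_len(n)) {
      if (is.na(cluster[i])) {
        fpkm[i, ] <- runif(p, 0, 9.99)
      } else {
        mu <- config$cluster_profiles[cluster[i], ]
        for (try in seq_len(100)) {
          v <- pmax(mu + rnorm(p, sd = config$noise_sd), 0)
          if (max(v) >= 10) break
          if (try == 100)
            stop("cluster profile too low to survive the filter",
                 call. = FALSE)
        }
        fpkm[i, ] <- v
      }
    }
    list(fpkm = fpkm,
         truth = data.frame(gene_id = ids, cluster = cluster,
                            stringsAsFactors = FALSE))
  })
}
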