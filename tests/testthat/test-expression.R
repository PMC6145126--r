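# FPKM filtering, transformation, family averaging, Pearson k-means.

test_that("low-expression filter is strict-below on every sample", {
  m <- rbind(low = c(9.99, 5, 0), edge = c(10.0, 3, 1), high = c(50, 60, 70))
  colnames(m) <- paste0("s", 1:3)
  fl <- filterLowExpression(m)
  expect_equal(fl$filtered, "low")
  expect_setequal(rownames(fl$retained), c("edge", "high"))
  # exact partition
  expect_equal(nrow(fl$retained) + length(fl$filtered), nrow(m))
  # monotone in the threshold
  fl5 <- filterLowExpression(m, threshold = 5)
  expect_true(all(fl5$filtered %in% fl$filtered))
  expect_error(filterLowExpression(m, threshold = 0), "> 0")
})

test_that("log transform is log2(FPKM + 1)", {
  expect_equal(logTransform(matrix(c(0, 1, 7))), matrix(c(0, 1, 3)))
  expect_error(logTransform(matrix(-1)), "negative")
})

test_that("family means average member profiles per sample", {
  m <- rbind(g1 = c(2, 8), g2 = c(4, 0), g3 = c(10, 10))
  colnames(m) <- c("s1", "s2")
  fam <- c(g1 = "FamA", g2 = "FamA", g3 = "FamB")
  fm <- familyMeanExpression(m, fam)
  expect_equal(fm["FamA", ], c(s1 = 3, s2 = 4))
  expect_equal(fm["FamB", ], c(s1 = 10, s2 = 10))   # single member unchanged
  # mean bounded by member min/max per sample
  expect_true(all(fm["FamA", ] >= apply(m[1:2, ], 2, min)))
  expect_true(all(fm["FamA", ] <= apply(m[1:2, ], 2, max)))
  # genes without a family are omitted, absent families too
  fm2 <- familyMeanExpression(m[1:2, , drop = FALSE], fam)
  expect_equal(rownames(fm2), "FamA")
})

test_that("noise-free planted clusters are recovered perfectly", {
  cfg <- simExpressionConfig(n_genes = 60, n_clusters = 3,
                             sample_labels = paste0("t", 1:8),
                             noise_sd = 0, frac_low_expressed = 0, seed = 2)
  d <- simExpressionData(cfg)
  km <- kmeansPearson(d$fpkm, k = 3, n_restarts = 10, seed = 5)
  ari <- mclust::adjustedRandIndex(
    km$cluster, d$truth$cluster[match(names(km$cluster), d$truth$gene_id)])
  expect_equal(ari, 1)
  # every gene profile equals its cluster mean exactly
  for (i in seq_len(nrow(d$fpkm))) {
    cl <- d$truth$cluster[i]
    expect_equal(unname(d$fpkm[d$truth$gene_id[i], ]),
                 unname(cfg$cluster_profiles[cl, ]))
  }
})

test_that("k = 1 returns the global mean centroid; bad k errors", {
  m <- matrix(rnorm(50, 10), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  km <- kmeansPearson(m, k = 1, n_restarts = 2, seed = 1)
  expect_true(all(km$cluster == 1))
  expect_equal(unname(km$centroids[1, ]), unname(colMeans(m)))
  expect_error(kmeansPearson(m, k = 0), "positive")
  expect_error(kmeansPearson(m, k = 11), "exceeds")
})

test_that("restart winner has the minimal objective and runs are deterministic", {
  cfg <- simExpressionConfig(n_genes = 80, n_clusters = 4,
                             sample_labels = paste0("t", 1:10),
                             noise_sd = 8, frac_low_expressed = 0, seed = 3)
  d <- simExpressionData(cfg)
  km <- kmeansPearson(d$fpkm, k = 4, n_restarts = 15, seed = 7)
  expect_equal(km$objective, min(km$restart_objectives))
  km2 <- kmeansPearson(d$fpkm, k = 4, n_restarts = 15, seed = 7)
  expect_identical(km, km2)
  km3 <- kmeansPearson(d$fpkm, k = 4, n_restarts = 15, seed = 8)
  expect_equal(km3$objective, min(km3$restart_objectives))
})

test_that("Pearson distance is invariant to positive affine rescaling", {
  cfg <- simExpressionConfig(n_genes = 40, n_clusters = 2,
                             sample_labels = paste0("t", 1:6),
                             noise_sd = 2, frac_low_expressed = 0, seed = 9)
  d <- simExpressionData(cfg)
  km <- kmeansPearson(d$fpkm, k = 2, n_restarts = 5, seed = 4)
  scaled <- d$fpkm
  scaled[1, ] <- 3.7 * scaled[1, ] + 11     # rescale one gene's profile
  km2 <- kmeansPearson(scaled, k = 2, n_restarts = 5, seed = 4)
  # partition is unchanged up to label permutation
  expect_equal(mclust::adjustedRandIndex(km$cluster, km2$cluster), 1)
})

test_that("zero-variance rows are dropped and reported", {
  m <- rbind(flat = rep(5, 6), g1 = rnorm(6, 10), g2 = rnorm(6, 10),
             g3 = rnorm(6, 10))
  colnames(m) <- paste0("s", 1:6)
  km <- kmeansPearson(m, k = 2, n_restarts = 3, seed = 1)
  expect_equal(km$dropped, "flat")
  expect_false("flat" %in% names(km$cluster))
})

test_that("the expression simulator honors its planted truth", {
  cfg <- simExpressionConfig(n_genes = 100, frac_low_expressed = 0.2,
                             noise_sd = 3, seed = 5)
  d <- simExpressionData(cfg)
  expect_true(all(d$fpkm >= 0))
  fl <- filterLowExpression(d$fpkm)
  expect_equal(length(fl$filtered), 20)
  expect_setequal(fl$filtered, d$truth$gene_id[is.na(d$truth$cluster)])
  # determinism
  d2 <- simExpressionData(cfg)
  expect_identical(d, d2)
  # config validation
  expect_error(simExpressionConfig(n_genes = 10, n_clusters = 3,
                                   cluster_sizes = c(5, 5, 5),
                                   frac_low_expressed = 0),
               "sum")
})
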