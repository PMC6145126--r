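# Pearson coexpression network: correlations, p-values, thresholds,
# degrees and components.

test_that("correlation basics via the network edge statistic", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9)
  expect_equal(cor(x, 2 * x + 1), 1)
  expect_equal(cor(x, -x), -1)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cor(a, b), manual, tolerance = 1e-12)
})

test_that("pccPvalue follows the t reference and its limits", {
  expect_equal(pccPvalue(0, 10), 1)
  expect_equal(pccPvalue(1, 10), 0)
  expect_equal(pccPvalue(-1, 10), 0)
  expect_error(pccPvalue(0.5, 2), ">= 3")
  # strictly decreasing in |r| at fixed n
  p <- pccPvalue(seq(0, 0.99, by = 0.01), 14)
  expect_true(all(diff(p) < 0))
  # two-sided symmetry
  expect_equal(pccPvalue(0.7, 14), pccPvalue(-0.7, 14))
  # agreement with cor.test
  ct <- cor.test(c(1, 2, 3, 5, 4, 7, 8, 6), c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(pccPvalue(unname(ct$estimate), 8), ct$p.value,
               tolerance = 1e-12)
})

test_that("the |r| threshold is strict", {
  # integer construction with exactly representable r = 0.8
  u <- c(1, 1, -1, -1, 0, 0)
  v <- c(1, -1, 1, -1, 0, 0)
  w <- c(0, 0, 0, 0, 1, -1)
  y <- 4 * u + 3 * v
  r <- cor(u, y)
  expect_equal(r, 0.8, tolerance = 1e-15)
  m <- rbind(u = u, y = y, w = w)
  colnames(m) <- paste0("s", 1:6)
  net <- buildCoexpressionNetwork(m, min_abs_pcc = r, alpha = 1)
  expect_false(any(net@edges$node_a == "u" & net@edges$node_b == "y"))
  net2 <- buildCoexpressionNetwork(m, min_abs_pcc = r - 1e-9, alpha = 1)
  expect_true(any(net2@edges$node_a == "u" & net2@edges$node_b == "y"))
})

test_that("edges are canonical, signed, and respect both thresholds", {
  set.seed(5)
  base <- sin(seq(0, 2 * pi, length.out = 14))
  m <- rbind(g1 = base + rnorm(14, sd = 0.05),
             g2 = base + rnorm(14, sd = 0.05),
             g3 = -base + rnorm(14, sd = 0.05),
             g4 = rnorm(14))
  colnames(m) <- paste0("s", 1:14)
  net <- buildCoexpressionNetwork(m)
  e <- networkEdges(net)
  expect_true(all(e$node_a < e$node_b))
  expect_true(all(abs(e$r) > 0.8))
  expect_true(all(e$p < 0.01))
  expect_true(all(e$sign == ifelse(e$r > 0, "positive", "negative")))
  pos <- e[e$node_a == "g1" & e$node_b == "g2", ]
  expect_equal(pos$sign, "positive")
  neg <- e[e$node_a == "g1" & e$node_b == "g3", ]
  expect_equal(neg$sign, "negative")
  # raising the threshold never adds edges
  net9 <- buildCoexpressionNetwork(m, min_abs_pcc = 0.9)
  k8 <- paste(networkEdges(net)$node_a, networkEdges(net)$node_b)
  k9 <- paste(networkEdges(net9)$node_a, networkEdges(net9)$node_b)
  expect_true(all(k9 %in% k8))
})

test_that("constant profiles are dropped, not propagated", {
  m <- rbind(flat = rep(3, 10), g1 = rnorm(10), g2 = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  net <- buildCoexpressionNetwork(m)
  expect_equal(net@dropped, "flat")
  expect_false("flat" %in% c(net@edges$node_a, net@edges$node_b))
})

test_that("degrees and components match the toy graph", {
  edges <- data.frame(node_a = c("a", "a", "b", "d"),
                      node_b = c("b", "c", "c", "e"),
                      r = c(0.9, 0.9, 0.9, -0.95),
                      p = rep(1e-5, 4),
                      sign = c("positive", "positive", "positive", "negative"),
                      stringsAsFactors = FALSE)
  dc <- degreeAndComponents(edges)
  expect_equal(sort(as.integer(dc$component_sizes)), c(2, 3))
  expect_equal(dc$n_components, 2)
  expect_equal(sort(unname(dc$degree[c("a", "b", "c")])), c(2, 2, 2))
  expect_equal(unname(dc$degree["d"]), 1)
  empty <- degreeAndComponents(edges[0, ])
  expect_equal(empty$n_nodes, 0)
  expect_equal(empty$n_components, 0)
})

test_that("planted coexpression modules come out as cliques/components", {
  set.seed(8)
  t24 <- seq_len(24)
  mod1 <- sin(2 * pi * t24 / 24)
  mod2 <- cos(2 * pi * t24 / 12)
  m <- rbind(
    do.call(rbind, lapply(1:5, function(i) 20 * mod1 + rnorm(24, sd = 0.3))),
    do.call(rbind, lapply(1:5, function(i) 20 * mod2 + rnorm(24, sd = 0.3))),
    do.call(rbind, lapply(1:4, function(i) rnorm(24, 10, 3))))
  rownames(m) <- c(paste0("m1_", 1:5), paste0("m2_", 1:5), paste0("bg", 1:4))
  colnames(m) <- paste0("s", t24)
  net <- buildCoexpressionNetwork(m)
  dc <- degreeAndComponents(net)
  comp <- dc$components
  # the two planted modules form two components with no background nodes
  expect_equal(dc$n_components, 2)
  expect_setequal(comp$node, c(paste0("m1_", 1:5), paste0("m2_", 1:5)))
  c1 <- unique(comp$component[grepl("^m1", comp$node)])
  c2 <- unique(comp$component[grepl("^m2", comp$node)])
  expect_length(c1, 1)
  expect_length(c2, 1)
  expect_false(c1 == c2)
})

test_that("gene-level and family-level matrices use the same code path", {
  set.seed(12)
  m <- matrix(rnorm(14 * 8, 20, 4), 8, 14,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:14)))
  fam <- setNames(rep(c("FamA", "FamB"), each = 4), rownames(m))
  fm <- familyMeanExpression(m, fam)
  net_gene <- buildCoexpressionNetwork(m)
  net_fam <- buildCoexpressionNetwork(fm)
  expect_s4_class(net_gene, "CoexpressionNetwork")
  expect_s4_class(net_fam, "CoexpressionNetwork")
  expect_equal(net_fam@params$n_samples, net_gene@params$n_samples)
})
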