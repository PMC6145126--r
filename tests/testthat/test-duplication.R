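# Tandem rule boundaries, oracle equivalence, collinear-block chaining.

.tandemFixture <- function(rows) {
  genes <- do.call(rbind, lapply(seq_along(rows), function(i)
    data.frame(gene_id = paste0("g", i), chrom = rows[[i]][["chrom"]],
               start = as.numeric(rows[[i]][["start"]]),
               end = as.numeric(rows[[i]][["end"]]),
               stringsAsFactors = FALSE)))
  genes
}

test_that("tandem rule boundaries: <=5 intervening (inclusive), <100 kb (strict)", {
  # adjacent same-family genes 5 kb apart -> tandem
  genes <- .tandemFixture(list(c(chrom = "c1", start = 1000, end = 2000),
                               c(chrom = "c1", start = 7000, end = 8000)))
  fams <- c(g1 = "F", g2 = "F")
  res <- callTandemDuplications(genes, fams)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$intervening_genes, 0)
  expect_equal(res$events$separation_bp, 5000)

  # exactly 5 intervening genes -> still tandem; 6 -> not
  mk <- function(n_between) {
    rows <- list(c(chrom = "c1", start = 1000, end = 2000))
    p <- 3000
    for (i in seq_len(n_between)) {
      rows[[length(rows) + 1]] <- c(chrom = "c1", start = p, end = p + 500)
      p <- p + 1000
    }
    rows[[length(rows) + 1]] <- c(chrom = "c1", start = p, end = p + 500)
    .tandemFixture(rows)
  }
  g5 <- mk(5)
  fams5 <- setNames(c("F", "F"), c("g1", g5$gene_id[nrow(g5)]))
  expect_equal(nrow(callTandemDuplications(g5, fams5)$events), 1)
  g6 <- mk(6)
  fams6 <- setNames(c("F", "F"), c("g1", g6$gene_id[nrow(g6)]))
  expect_equal(nrow(callTandemDuplications(g6, fams6)$events), 0)

  # separation exactly 100,000 bp -> not tandem; one bp less -> tandem
  genes <- .tandemFixture(list(c(chrom = "c1", start = 1000, end = 2000),
                               c(chrom = "c1", start = 102000, end = 103000)))
  expect_equal(nrow(callTandemDuplications(genes, c(g1 = "F", g2 = "F"))$events), 0)
  genes$start[2] <- 101999
  expect_equal(nrow(callTandemDuplications(genes, c(g1 = "F", g2 = "F"))$events), 1)

  # different chromosomes never pair
  genes <- .tandemFixture(list(c(chrom = "c1", start = 1000, end = 2000),
                               c(chrom = "c2", start = 3000, end = 4000)))
  expect_equal(nrow(callTandemDuplications(genes, c(g1 = "F", g2 = "F"))$events), 0)
})

test_that("tandem caller equals the exhaustive pairwise scan on random layouts", {
  for (seed in 1:10) {
    lay <- randomGeneLayout(seed)
    res <- callTandemDuplications(lay$genes, lay$families)
    got <- sort(paste(res$events$gene_a, res$events$gene_b, sep = "|"))
    want <- oracleTandemPairs(lay$genes, lay$families)
    expect_identical(got, want)
    # symmetric storage: canonical order, no duplicates, irreflexive
    expect_true(all(res$events$gene_a < res$events$gene_b))
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("genes with missing coordinates are excluded with a warning", {
  genes <- .tandemFixture(list(c(chrom = "c1", start = 1000, end = 2000),
                               c(chrom = "c1", start = 4000, end = 5000)))
  genes$start[2] <- NA
  expect_warning(res <- callTandemDuplications(genes, c(g1 = "F", g2 = "F")),
                 "missing")
  expect_equal(nrow(res$events), 0)
})

test_that("collinear chains: perfect order gives one block, noise gives none", {
  perfect <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10),
                        chrom_a = "c1", chrom_b = "c2",
                        rank_a = 1:10, rank_b = 1:10,
                        stringsAsFactors = FALSE)
  bl <- findCollinearBlocks(perfect)
  expect_equal(length(unique(bl$block_id)), 1)
  expect_equal(nrow(bl), 10)

  inverted <- perfect
  inverted$rank_b <- 10:1
  bl <- findCollinearBlocks(inverted)
  expect_equal(nrow(bl), 10)
  expect_equal(unique(bl$orientation), "inverted")

  set.seed(3)
  repeat {  # draw a permutation with no monotone run of length 5
    perm <- sample(10)
    if (oracleLongestChain(1:10, perm, max_gap = 25) < 5) break
  }
  noise <- perfect
  noise$rank_b <- perm
  expect_equal(nrow(findCollinearBlocks(noise)), 0)
})

test_that("detected block sizes equal the brute-force longest chain", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(8:14, 1)
    anchors <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                          chrom_a = "c1", chrom_b = "c2",
                          rank_a = sample(40, n), rank_b = sample(40, n),
                          stringsAsFactors = FALSE)
    best <- oracleLongestChain(anchors$rank_a, anchors$rank_b, max_gap = 25)
    bl <- findCollinearBlocks(anchors, min_block = 5, max_gap = 25)
    if (best < 5) {
      expect_equal(nrow(bl), 0)
    } else {
      first <- bl[bl$block_id == 1, ]
      expect_equal(nrow(first), best)
      # chain strictly monotone on both chromosomes
      expect_true(all(diff(first$rank_a) > 0))
      expect_true(all(diff(first$rank_b) > 0) || all(diff(first$rank_b) < 0))
    }
    # no anchor in two blocks
    expect_false(anyDuplicated(paste(bl$gene_a, bl$gene_b)) > 0)
  }
})

test_that("planted blocks and arrays are recovered exactly from gen output", {
  sim <- simKinomeGenome(simGenomeConfig(n_collinear_blocks = 3,
                                         block_length = 7,
                                         n_tandem_arrays = 4,
                                         tandem_array_size = 3,
                                         n_chromosomes = 6, seed = 31))
  bl <- findCollinearBlocks(sim$anchors)
  expect_equal(length(unique(bl$block_id)), 3)
  expect_setequal(paste(bl$gene_a, bl$gene_b),
                  paste(sim$truth$blocks$gene_a, sim$truth$blocks$gene_b))
  td <- callTandemDuplications(
    sim$models$genes,
    setNames(sim$truth$kinases$family, sim$truth$kinases$gene_id))
  expect_equal(length(unique(td$arrays$array_id)), 4)
  expect_setequal(td$arrays$gene_id, sim$truth$tandem_arrays$gene_id)
})

test_that("duplication origin labels cover tandem, segmental, both, none", {
  events <- data.frame(gene_a = "g1", gene_b = "g2", chrom = "c1",
                       family = "F", intervening_genes = 0,
                       separation_bp = 1000, stringsAsFactors = FALSE)
  tandem <- list(events = events,
                 arrays = data.frame(gene_id = c("g1", "g2"), array_id = 1))
  blocks <- data.frame(block_id = 1, gene_a = "g2", gene_b = "g9",
                       chrom_a = "c1", chrom_b = "c2", rank_a = 1, rank_b = 1,
                       orientation = "same", stringsAsFactors = FALSE)
  lab <- classifyDuplication(c("g1", "g2", "g9", "gX"), tandem, blocks)
  expect_equal(unname(lab), c("tandem", "both", "segmental", "none"))
  s <- summarizeDuplication(lab, tandem, blocks)
  expect_equal(s$n_tandem_genes, 2)
  expect_equal(s$n_segmental_genes, 2)
  expect_equal(s$tandem_gene_pct, 50)
})
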