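# Domain-hit parsing, the identification filter, family assignment,
# domain/intron counting and catalog summaries.

test_that("readDomainHits parses the per-domain dialect", {
  path <- writeHitLines(c(
    "# protein model mlen seqE domE bit hf ht af at",
    "p1\tPkinase\t260\t1e-20\t1e-18\t250.3\t1\t260\t10\t280",
    "",
    "p2\tPkinase_Tyr\t270\t2e-9\t5e-8\t88.1\t20\t170\t5\t160"))
  hits <- readDomainHits(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$protein_id, c("p1", "p2"))
  expect_equal(hits$hmm_from, c(1, 20))
  expect_equal(hits$ali_to, c(280, 160))
  expect_equal(hits$dom_evalue, c(1e-18, 5e-8))
})

test_that("readDomainHits handles empty files and malformed rows", {
  expect_equal(nrow(readDomainHits(writeHitLines("# only a comment"))), 0)
  # row violating hmm_to <= model_length is rejected with a line number
  path <- writeHitLines(c(
    "p1\tPkinase\t260\t1e-20\t1e-18\t250\t1\t300\t10\t280",
    "p2\tPkinase\t260\t1e-20\t1e-18\t250\t1\t200\t10\t210"))
  expect_warning(hits <- readDomainHits(path), "line")
  expect_equal(hits$protein_id, "p2")
  # uniformly truncated tables name the missing columns
  expect_error(readDomainHits(writeHitLines("p1\tPkinase\t260")),
               "seq_evalue")
})

test_that("the identification filter applies strict E-value and inclusive coverage", {
  # coverage exactly 50% of the model is accepted
  h <- makeHit(model_length = 260, hmm_from = 1, hmm_to = 130,
               dom_evalue = 1e-10)
  expect_equal(nrow(filterKinaseHits(h)), 1)
  # one model position fewer (coverage 129/260) is rejected
  h <- makeHit(model_length = 260, hmm_from = 1, hmm_to = 129,
               dom_evalue = 1e-10)
  expect_equal(nrow(filterKinaseHits(h)), 0)
  # E-value exactly at the cutoff is rejected (strict <)
  h <- makeHit(hmm_from = 1, hmm_to = 234, dom_evalue = 1e-5)
  expect_equal(nrow(filterKinaseHits(h)), 0)
  h$dom_evalue <- 0.999e-5
  expect_equal(nrow(filterKinaseHits(h)), 1)
  # the sequence-level variant filters on seq_evalue instead
  h <- makeHit(seq_evalue = 1e-3, dom_evalue = 1e-10)
  expect_equal(nrow(filterKinaseHits(h, evalue_on = "sequence")), 0)
})

test_that("relaxing either filter threshold never removes accepted hits", {
  set.seed(11)
  hits <- do.call(rbind, lapply(seq_len(200), function(i) {
    ml <- sample(100:400, 1)
    hf <- sample(1:50, 1)
    makeHit(protein_id = paste0("p", i), model_length = ml, hmm_from = hf,
            hmm_to = min(ml, hf + sample(30:400, 1)),
            dom_evalue = 10^runif(1, -30, 0))
  }))
  strict <- filterKinaseHits(hits, 1e-5, 0.5)
  for (args in list(list(1e-3, 0.5), list(1e-5, 0.3), list(1e-2, 0.1))) {
    relaxed <- filterKinaseHits(hits, args[[1]], args[[2]])
    expect_true(all(rownames(strict) %in% rownames(relaxed)))
  }
})

test_that("family assignment is argmax with flagged lexicographic ties", {
  expect_equal(assignFamily(c(FamA = 300, FamB = 120))$family, "FamA")
  un <- assignFamily(numeric(0))
  expect_equal(un$family, "unclassified")
  expect_equal(un$group, "unclassified")
  tie <- assignFamily(c(FamB = 200, FamA = 200))
  expect_equal(tie$family, "FamA")
  expect_true(tie$tie)
  expect_equal(tie$margin, 0)
  m <- assignFamily(c(FamA = 300, FamB = 120, FamC = 250))
  expect_equal(m$margin, 50)
  expect_equal(familyGroup("RLK-Pelle_DLSV"), "RLK")
  expect_equal(familyGroup("CAMK_CAMKL-CHK1"), "CAMK")
})

test_that("kinase-domain counting merges split alignments", {
  two <- rbind(makeHit(ali_from = 10, ali_to = 300),
               makeHit(ali_from = 400, ali_to = 690))
  expect_equal(countKinaseDomains(two), 2)
  overlapping <- rbind(makeHit(ali_from = 10, ali_to = 300),
                       makeHit(ali_from = 20, ali_to = 310))
  expect_equal(countKinaseDomains(overlapping), 1)
  five <- do.call(rbind, lapply(0:4, function(k)
    makeHit(ali_from = 10 + 300 * k, ali_to = 290 + 300 * k)))
  expect_equal(countKinaseDomains(five), 5)
  # sub-50% overlap of the shorter interval does not merge
  apart <- rbind(makeHit(ali_from = 1, ali_to = 100),
                 makeHit(ali_from = 60, ali_to = 300))
  expect_equal(countKinaseDomains(apart), 2)
  expect_equal(countKinaseDomains(makeHit()[0, ]), 0)
})

test_that("intron counts come from the representative transcript", {
  expect_equal(countIntrons(data.frame(start = 1, end = 100)), 0)
  expect_equal(countIntrons(data.frame(start = seq(1, 6701, 100)[1:68],
                                       end = seq(50, 6750, 100)[1:68])), 67)
  expect_error(countIntrons(data.frame(start = numeric(0),
                                       end = numeric(0))), "exons")
  # gene with 3-exon and 5-exon isoforms, longer CDS on the 5-exon one
  gff <- writeTinyGFF(list(gA = list(
    chrom = "chr1", strand = "+",
    isoforms = list(
      gA.1 = data.frame(start = c(1, 301, 601), end = c(99, 399, 699)),
      gA.2 = data.frame(start = c(1, 201, 401, 601, 801),
                        end = c(150, 350, 550, 750, 950))))))
  hits <- makeHit(protein_id = "gA.2")
  cat_obj <- buildKinaseCatalog(hits, gff)
  expect_equal(catalogRecords(cat_obj)$intron_count, 4)
})

test_that("catalog summaries conserve totals and tally scaffolds apart", {
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    protein_id = sprintf("g%02d.1", 1:10),
    family = c(rep("FamA", 6), rep("FamB", 3), "unclassified"),
    group = c(rep("FamA", 6), rep("FamB", 3), "unclassified"),
    n_kinase_domains = c(rep(1, 7), 2, 2, 3),
    intron_count = 0:9,
    chrom = c(rep("chr1", 5), rep("chr2", 3), "scaffold_7", "scaffold_9"),
    is_scaffold = c(rep(FALSE, 8), TRUE, TRUE),
    start = 1:10, end = 11:20, strand = "+",
    stringsAsFactors = FALSE)
  s <- summarizeCatalog(rec, genome_size = 100)
  expect_equal(as.integer(s$family_counts), c(6, 3))
  expect_equal(s$n_classified + s$n_unclassified, 10)
  expect_equal(sum(s$family_counts) + s$n_unclassified, s$n_kinases)
  expect_equal(sum(s$chromosome_counts) + s$n_scaffold_genes, s$n_kinases)
  expect_equal(s$n_scaffold_genes, 2)
  expect_equal(s$n_multidomain, 3)
  expect_equal(s$kinome_fraction_pct, 10)
})

test_that("on synthetic genomes the catalog equals the planted truth", {
  sim <- simKinomeGenome(simGenomeConfig(n_decoys = 50, decoy_evalue = 1e-3,
                                         seed = 23))
  cat_obj <- buildKinaseCatalog(sim$hits, sim$models)
  rec <- catalogRecords(cat_obj)
  expect_setequal(rec$gene_id, sim$truth$kinases$gene_id)
  # zero false positives: no decoy is ever identified
  expect_length(intersect(rec$gene_id, sim$truth$decoys$gene_id), 0)
  # family and group labels match the planted truth
  m <- match(rec$gene_id, sim$truth$kinases$gene_id)
  expect_equal(rec$family, sim$truth$kinases$family[m])
  expect_equal(rec$group, sim$truth$kinases$group[m])
  # intron counts match the planted exon structures
  expect_equal(rec$intron_count,
               unname(sim$truth$intron_counts[rec$gene_id]))
})
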