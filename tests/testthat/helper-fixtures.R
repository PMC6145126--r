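# Small fixture builders shared across test files.

makeHit <- function(protein_id = "p1", model_name = "Pkinase",
                    model_length = 260, seq_evalue = 1e-12,
                    dom_evalue = 1e-10, bit_score = 200,
                    hmm_from = 1, hmm_to = 260, ali_from = 1, ali_to = 280) {
  data.frame(protein_id = protein_id, model_name = model_name,
             model_length = model_length, seq_evalue = seq_evalue,
             dom_evalue = dom_evalue, bit_score = bit_score,
             hmm_from = hmm_from, hmm_to = hmm_to,
             ali_from = ali_from, ali_to = ali_to,
             stringsAsFactors = FALSE)
}

writeHitLines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Minimal GFF3 text for a set of genes given as
# list(gene_id = list(chrom=, strand=, isoforms = list(tx_id = exon df)))
writeTinyGFF <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (gid in names(genes)) {
    g <- genes[[gid]]
    all_ex <- do.call(rbind, g$isoforms)
    lines <- c(lines, sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, min(all_ex$start), max(all_ex$end), g$strand, gid))
    for (tid in names(g$isoforms)) {
      ex <- g$isoforms[[tid]]
      lines <- c(lines, sprintf(
        "%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(ex$start), max(ex$end), g$strand, tid, gid))
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, ex$start[k], ex$end[k], g$strand, tid, k, tid))
        lines <- c(lines, sprintf(
          "%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
          g$chrom, ex$start[k], ex$end[k], g$strand, tid, k, tid))
      }
    }
  }
  writeLines(lines, path)
  path
}

# Random gene layout for tandem-oracle comparisons: one data.frame of gene
# coordinates plus random family labels for a kinase subset.
randomGeneLayout <- function(seed, n_chrom = 2, n_genes = 30, n_fam = 4) {
  set.seed(seed)
  rows <- list()
  gid <- 0
  for (ch in seq_len(n_chrom)) {
    pos <- 1
    for (i in seq_len(n_genes)) {
      gid <- gid + 1
      pos <- pos + sample(c(500:5e4, 9e4:1.3e5), 1)
      len <- sample(1e3:5e3, 1)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%03d", gid), chrom = paste0("chr", ch),
        start = pos, end = pos + len, stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  genes <- do.call(rbind, rows)
  kin <- sample(genes$gene_id, round(nrow(genes) * 0.6))
  families <- setNames(sample(paste0("F", seq_len(n_fam)), length(kin),
                              replace = TRUE), kin)
  list(genes = genes, families = families)
}
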