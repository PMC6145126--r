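# Independent reference implementations used to cross-check the package.
# Deliberately written from first principles with different code structure
# than the implementations they verify.

.ORACLE_CODE <- Biostrings::GENETIC_CODE
.ORACLE_BASES <- c("A", "C", "G", "T")

oracleAllCodons <- function() {
  g <- expand.grid(.ORACLE_BASES, .ORACLE_BASES, .ORACLE_BASES,
                   stringsAsFactors = FALSE)
  paste0(g[, 1], g[, 2], g[, 3])
}

oracleSenseCodons <- function() {
  cods <- oracleAllCodons()
  cods[.ORACLE_CODE[cods] != "*"]
}

# Fraction of synonymous sites of a codon: per position, synonymous
# single-base changes over non-stop single-base changes.
oracleCodonS <- function(codon) {
  letters3 <- substring(codon, 1:3, 1:3)
  aa <- .ORACLE_CODE[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (base in .ORACLE_BASES) {
      if (base == letters3[pos]) next
      mut <- letters3
      mut[pos] <- base
      mut_codon <- paste0(mut[1], mut[2], mut[3])
      mut_aa <- .ORACLE_CODE[[mut_codon]]
      if (mut_aa == "*") next
      valid <- valid + 1
      if (mut_aa == aa) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# Pathway-averaged synonymous/nonsynonymous differences via explicit
# recursive enumeration of all orderings, skipping stop intermediates.
oracleCodonDiff <- function(a, b) {
  walk <- function(cur, remaining, allow_stop) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (ix in seq_along(remaining)) {
      pos <- remaining[ix]
      nxt <- substring(cur, 1:3, 1:3)
      nxt[pos] <- substring(b, pos, pos)
      nxt_codon <- paste(nxt, collapse = "")
      if (!allow_stop && .ORACLE_CODE[[nxt_codon]] == "*" && nxt_codon != b)
        next
      step <- if (.ORACLE_CODE[[cur]] == .ORACLE_CODE[[nxt_codon]])
        c(1, 0) else c(0, 1)
      for (tail in walk(nxt_codon, remaining[-ix], allow_stop))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  diffs <- which(substring(a, 1:3, 1:3) != substring(b, 1:3, 1:3))
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  paths <- walk(a, diffs, allow_stop = FALSE)
  if (length(paths) == 0) paths <- walk(a, diffs, allow_stop = TRUE)
  m <- Reduce(`+`, paths) / length(paths)
  c(sd = m[1], nd = m[2])
}

# Full NG86 + JC reference on two equal-length stop-free CDS strings.
oracleKaKs <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a); cb <- split3(cds_b)
  Sa <- sum(vapply(ca, oracleCodonS, numeric(1)))
  Sb <- sum(vapply(cb, oracleCodonS, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in seq_along(ca)) {
    d <- oracleCodonDiff(ca[i], cb[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  pS <- sd_tot / S
  pN <- nd_tot / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd_tot, Nd = nd_tot, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# Exhaustive per-chromosome pairwise scan implementing the tandem rule.
oracleTandemPairs <- function(genes, families, max_intervening = 5,
                              max_separation_bp = 1e5) {
  res <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    g <- g[order(g$start, g$end, g$gene_id), ]
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(g))) {
        if (j <= i) next
        fa <- families[g$gene_id[i]]
        fb <- families[g$gene_id[j]]
        if (is.na(fa) || is.na(fb) || fa != fb) next
        if (fa == "unclassified") next
        if (j - i - 1 > max_intervening) next
        if (g$start[j] - g$end[i] >= max_separation_bp) next
        res[[length(res) + 1]] <-
          sort(c(g$gene_id[i], g$gene_id[j]))
      }
    }
  }
  if (length(res) == 0) return(character(0))
  sort(vapply(res, paste, character(1), collapse = "|"))
}

# Brute-force longest doubly monotone anchor chain (either orientation)
# under the rank-gap constraint, by exhaustive recursion.
oracleLongestChain <- function(rank_a, rank_b, max_gap = 25) {
  n <- length(rank_a)
  if (n == 0) return(0L)
  best <- 0L
  extend <- function(last, used_len, dir_b) {
    best <<- max(best, used_len)
    for (i in seq_len(n)) {
      da <- rank_a[i] - rank_a[last]
      db <- (rank_b[i] - rank_b[last]) * dir_b
      if (da <= 0 || db <= 0) next
      if (da - 1 > max_gap || db - 1 > max_gap) next
      extend(i, used_len + 1L, dir_b)
    }
  }
  for (start in seq_len(n)) {
    extend(start, 1L, 1)
    extend(start, 1L, -1)
  }
  best
}
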