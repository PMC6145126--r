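# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Sites: at each of the three codon positions the synonymous fraction is the
# number of single-base changes that preserve the amino acid, divided by the
# number of single-base changes that do not create a stop codon.  Differences
# between codons differing at 2-3 positions are averaged over all mutational
# pathways of single-base steps, excluding pathways that pass through a stop
# codon.  Proportions are corrected with d = -3/4 log(1 - 4p/3).

.kk <- new.env(parent = emptyenv())

.geneticCode <- function() {
  if (is.null(.kk$code)) .kk$code <- Biostrings::GENETIC_CODE
  .kk$code
}

.senseCodons <- function() {
  code <- .geneticCode()
  names(code)[code != "*"]
}

.isStop <- function(codon) .geneticCode()[codon] == "*"

# Single-base neighbors of a codon (9 of them).
.codonNeighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  sp <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(bases, sp[pos])) {
      nb <- sp
      nb[pos] <- b
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

# Per-codon synonymous site count (scalar s in [0, 3]); n = 3 - s.
.codonSitesOne <- function(codon) {
  code <- .geneticCode()
  aa <- code[[codon]]
  sp <- strsplit(codon, "")[[1]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in setdiff(bases, sp[pos])) {
      nb <- sp
      nb[pos] <- b
      nbc <- paste(nb, collapse = "")
      if (code[[nbc]] == "*") next
      valid <- valid + 1L
      if (code[[nbc]] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

.siteTable <- function() {
  if (is.null(.kk$sites)) {
    sense <- .senseCodons()
    .kk$sites <- vapply(sense, .codonSitesOne, numeric(1))
  }
  .kk$sites
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts the fractional number of synonymous (\code{s}) and nonsynonymous
#' (\code{n}) sites of a sense codon under the standard genetic code,
#' following the Nei-Gojobori (1986) convention: at each position the
#' synonymous fraction is computed over the single-base changes that do not
#' produce a stop codon, and \code{s + n = 3}.
#'
#' @param codon A single 3-letter character string (A/C/G/T), a sense codon.
#' @return Named numeric vector \code{c(s = , n = )}.
#' @examples
#' codonSites("GGG")  # fourfold-degenerate third position: s = 1
#' codonSites("TTT")  # only TTC synonymous: s = 1/3
#' @export
codonSites <- function(codon) {
  codon <- toupper(as.character(codon))
  if (length(codon) != 1L || nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("'codon' must be a single 3-letter ACGT string", call. = FALSE)
  if (.isStop(codon)) stop("stop codon has no site counts", call. = FALSE)
  s <- .siteTable()[[codon]]
  c(s = s, n = 3 - s)
}

# Pathway-averaged (sd, nd) for one codon pair.
.codonDiffOne <- function(a, b) {
  code <- .geneticCode()
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  diffpos <- which(pa != pb)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(diffpos),
    "2" = list(diffpos, rev(diffpos)),
    "3" = {
      p <- diffpos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  score <- function(path, allow_stop) {
    cur <- pa
    sd <- 0
    nd <- 0
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- pb[pos]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (!allow_stop && code[[c2]] == "*" && c2 != b) return(NULL)
      if (code[[c1]] == code[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, score, allow_stop = FALSE))
  if (length(res) == 0L)  # all pathways stop-blocked: fall back to all paths
    res <- lapply(perms, score, allow_stop = TRUE)
  m <- colMeans(do.call(rbind, res))
  c(sd = m[1], nd = m[2])
}

.diffTables <- function() {
  if (is.null(.kk$sd)) {
    sense <- .senseCodons()
    n <- length(sense)
    sd <- matrix(0, n, n, dimnames = list(sense, sense))
    nd <- sd
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        v <- .codonDiffOne(sense[i], sense[j])
        sd[i, j] <- sd[j, i] <- v[["sd"]]
        nd[i, j] <- nd[j, i] <- v[["nd"]]
      }
    }
    .kk$sd <- sd
    .kk$nd <- nd
  }
  list(sd = .kk$sd, nd = .kk$nd)
}

#' Pathway-averaged substitution counts between two codons
#'
#' Classifies the differences between two sense codons into synonymous
#' (\code{sd}) and nonsynonymous (\code{nd}) changes.  Codons differing at
#' two or three positions are averaged over all orderings of single-base
#' steps; pathways passing through a stop codon are excluded (if every
#' pathway is blocked, all pathways are used).  Always
#' \code{sd + nd == } number of differing positions.
#'
#' @param codon_a,codon_b Sense codons as 3-letter strings.
#' @return Named numeric vector \code{c(sd = , nd = )}.
#' @examples
#' codonDifferences("TTT", "TTC")  # synonymous: c(1, 0)
#' codonDifferences("TTT", "GTA")
#' @export
codonDifferences <- function(codon_a, codon_b) {
  a <- toupper(as.character(codon_a)); b <- toupper(as.character(codon_b))
  for (x in c(a, b))
    if (length(x) != 1L || nchar(x) != 3L || grepl("[^ACGT]", x))
      stop("codons must be 3-letter ACGT strings", call. = FALSE)
  if (.isStop(a) || .isStop(b)) stop("stop codons are not comparable", call. = FALSE)
  .codonDiffOne(a, b)
}

.splitCodons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Align two coding sequences codon by codon
#'
#' Pairs the codons of two CDS either directly (equal-length, gapless
#' sequences) or through a supplied protein alignment, whose gap columns are
#' dropped and whose residues must match the translations of the CDS.
#' A shared terminal stop codon is dropped; internal stop codons are errors.
#'
#' @param cds_a,cds_b Character strings or \code{DNAString}s; lengths must be
#'   multiples of 3.
#' @param protein_alignment Optional character vector of two aligned protein
#'   sequences (same length, \code{-} for gaps).
#' @return A list with character vectors \code{a} and \code{b} of aligned
#'   codons (equal length, no gaps, no stops).
#' @export
codonAlign <- function(cds_a, cds_b, protein_alignment = NULL) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  for (x in list(a, b)) {
    if (nchar(x) %% 3 != 0)
      stop("CDS length is not a multiple of 3", call. = FALSE)
    if (grepl("[^ACGT]", x))
      stop("CDS contains non-ACGT characters", call. = FALSE)
  }
  ca <- .splitCodons(a)
  cb <- .splitCodons(b)
  if (is.null(protein_alignment)) {
    if (length(ca) != length(cb))
      stop("unequal CDS lengths require a protein alignment", call. = FALSE)
  } else {
    if (length(protein_alignment) != 2L)
      stop("'protein_alignment' must contain two sequences", call. = FALSE)
    pa <- strsplit(toupper(protein_alignment[1]), "")[[1]]
    pb <- strsplit(toupper(protein_alignment[2]), "")[[1]]
    if (length(pa) != length(pb))
      stop("aligned protein sequences differ in length", call. = FALSE)
    keep <- pa != "-" & pb != "-"
    ia <- cumsum(pa != "-")
    ib <- cumsum(pb != "-")
    if (max(ia) != length(ca) || max(ib) != length(cb))
      stop("protein alignment does not match CDS lengths", call. = FALSE)
    code <- .geneticCode()
    ta <- unname(code[ca]); tb <- unname(code[cb])
    if (!all(ta[ia[pa != "-"]] == pa[pa != "-"]) ||
        !all(tb[ib[pb != "-"]] == pb[pb != "-"]))
      stop("protein alignment does not match CDS translations", call. = FALSE)
    ca <- ca[ia[keep]]
    cb <- cb[ib[keep]]
  }
  # shared terminal stop tolerated, dropped
  n <- length(ca)
  if (n > 0 && .isStop(ca[n]) && .isStop(cb[n])) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  if (any(.isStop(ca)) || any(.isStop(cb)))
    stop("internal stop codon in CDS", call. = FALSE)
  list(a = ca, b = cb)
}

# Jukes-Cantor correction; NA when the proportion is at or beyond saturation.
.jcCorrect <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Ka/Ks for a pair of coding sequences (Nei-Gojobori 1986)
#'
#' Estimates the number of synonymous substitutions per synonymous site
#' (\code{Ks}) and nonsynonymous substitutions per nonsynonymous site
#' (\code{Ka}) between two aligned CDS, using NG86 site and
#' pathway-averaged difference counting with a Jukes-Cantor multiple-hit
#' correction, and classifies the selective regime from Ka/Ks
#' (\code{< 1} purifying, \code{= 1} neutral, \code{> 1} positive).
#' Site counts are averaged over the two sequences.  The result is
#' symmetric in the argument order.
#'
#' @inheritParams codonAlign
#' @return A list with elements \code{S}, \code{N} (fractional site counts),
#'   \code{Sd}, \code{Nd} (difference counts), \code{pS}, \code{pN},
#'   \code{Ks}, \code{Ka} (\code{NA} when the proportion is saturated,
#'   p >= 3/4), \code{ratio} (Ka/Ks; \code{NA} when Ks is 0 or undefined),
#'   \code{selection} (one of \code{"purifying"}, \code{"neutral"},
#'   \code{"positive"}, \code{"undefined"}), and \code{n_codons}.
#' @examples
#' p <- simCodonPair(simCodonPairConfig(n_codons = 200, target_ks = 0.3,
#'                                      target_ka = 0.05, seed = 1))
#' kaKs(p$cds_a, p$cds_b)
#' @export
kaKs <- function(cds_a, cds_b, protein_alignment = NULL) {
  al <- codonAlign(cds_a, cds_b, protein_alignment)
  nc <- length(al$a)
  if (nc == 0L) stop("empty codon alignment", call. = FALSE)
  st <- .siteTable()
  sA <- sum(st[al$a])
  sB <- sum(st[al$b])
  S <- (sA + sB) / 2
  N <- 3 * nc - S
  dt <- .diffTables()
  idx <- cbind(match(al$a, rownames(dt$sd)), match(al$b, colnames(dt$sd)))
  Sd <- sum(dt$sd[idx])
  Nd <- sum(dt$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- .jcCorrect(pS)
  Ka <- .jcCorrect(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  selection <- if (is.na(ratio)) "undefined"
  else if (abs(ratio - 1) <= 1e-9) "neutral"
  else if (ratio < 1) "purifying"
  else "positive"
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, ratio = ratio, selection = selection,
       n_codons = nc)
}

#' Ka/Ks for a table of gene pairs
#'
#' Applies \code{\link{kaKs}} to each pair of a pair list, looking the CDS up
#' in a named sequence set.
#'
#' @param pairs A data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param cds A named \code{DNAStringSet} or named character vector of CDS.
#' @return A data.frame with one row per pair: identifiers, \code{Ka},
#'   \code{Ks}, \code{ratio} and \code{selection}.
#' @export
kaKsTable <- function(pairs, cds) {
  cds <- setNames(as.character(cds), names(cds))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing) > 0)
    stop("CDS missing for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- kaKs(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
               selection = r$selection, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of Ks values in fixed-width bins
#'
#' Bins defined (non-missing) Ks values into half-open intervals
#' \code{[k*w, (k+1)*w)}, the binning used to date duplication cohorts.
#'
#' @param ks Numeric vector of Ks values (\code{NA} = undefined, excluded
#'   and tallied separately).
#' @param bin_width Positive bin width (default 0.1).
#' @return A list with a data.frame \code{bins} (\code{lower}, \code{upper},
#'   \code{count}), \code{n_undefined}, and \code{peak} (the lower bounds of
#'   the maximal-count bins; empty when there are no defined values).
#' @examples
#' ksHistogram(c(0.25, 0.27, 1.15))
#' @export
ksHistogram <- function(ks, bin_width = 0.1) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a positive number", call. = FALSE)
  ks <- as.numeric(ks)
  und <- sum(is.na(ks))
  v <- ks[!is.na(ks)]
  if (length(v) == 0L)
    return(list(bins = data.frame(lower = numeric(0), upper = numeric(0),
                                  count = integer(0)),
                n_undefined = und, peak = numeric(0)))
  if (any(v < 0)) stop("negative Ks values", call. = FALSE)
  idx <- floor(v / bin_width)
  tab <- table(idx)
  k <- as.numeric(names(tab))
  bins <- data.frame(lower = k * bin_width, upper = (k + 1) * bin_width,
                     count = as.integer(tab))
  bins <- bins[order(bins$lower), , drop = FALSE]
  rownames(bins) <- NULL
  peak <- bins$lower[bins$count == max(bins$count)]
  list(bins = bins, n_undefined = und, peak = peak)
}
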