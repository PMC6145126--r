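# Alternative-splicing event classification from transcript models.
#
# Elementary pairwise events between two isoforms of one gene:
#   intron_retention - an intron of one isoform fully inside an exon of the
#     other;
#   alt_acceptor / alt_donor - two overlapping introns sharing the donor
#     (5') / acceptor (3') boundary and differing at the other;
#   exon_skipping - an exon of one isoform strictly inside a single intron
#     of the other, with the flanking introns sharing that intron's donor
#     and acceptor;
#   other - overlapping introns differing at both boundaries that fit none
#     of the above; these make the gene-level call "complex".
# UTR-only differences (identical intron chains) are not events.

.checkExons <- function(exons) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% colnames(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) == 0L) stop("transcript has no exons", call. = FALSE)
  if (any(exons$end < exons$start)) stop("exon end < start", call. = FALSE)
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript", call. = FALSE)
  exons
}

#' Intron intervals of a transcript
#'
#' Gaps between consecutive exons, with strand-resolved donor (5') and
#' acceptor (3') boundaries: on the plus strand the donor is the intron
#' start, on the minus strand the intron end.
#'
#' @param exons data.frame of exon \code{start}, \code{end} (1-based,
#'   inclusive, non-overlapping).
#' @param strand \code{"+"} or \code{"-"}.
#' @return data.frame with \code{start}, \code{end}, \code{donor},
#'   \code{acceptor} (zero rows for single-exon transcripts).
#' @export
intronsOf <- function(exons, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  exons <- .checkExons(exons)
  n <- nrow(exons)
  if (n == 1L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      donor = numeric(0), acceptor = numeric(0)))
  start <- exons$end[-n] + 1
  end <- exons$start[-1] - 1
  data.frame(start = start, end = end,
             donor = if (strand == "+") start else end,
             acceptor = if (strand == "+") end else start)
}

.intronKey <- function(introns) paste(introns$start, introns$end)

#' Classify elementary splicing events between two isoforms
#'
#' Compares the intron chains of two isoforms of one gene and returns the
#' elementary alternative-splicing events distinguishing them (see the
#' definitions in the package overview).  The result is symmetric in the
#' argument order; isoform direction is recorded as metadata only.
#'
#' @param exons_a,exons_b Exon tables (\code{start}, \code{end}) of the two
#'   isoforms.
#' @param strand Shared strand of the gene.
#' @return data.frame of events: \code{type} (\code{intron_retention},
#'   \code{alt_acceptor}, \code{alt_donor}, \code{exon_skipping},
#'   \code{other}), \code{start}, \code{end} (the affected interval) and
#'   \code{in_isoform} (which isoform carries the distinguishing feature;
#'   metadata, normalized away when comparing event sets).
#' @export
classifyPairEvents <- function(exons_a, exons_b, strand = "+") {
  ia <- intronsOf(exons_a, strand)
  ib <- intronsOf(exons_b, strand)
  ea <- .checkExons(exons_a)
  eb <- .checkExons(exons_b)
  ka <- .intronKey(ia)
  kb <- .intronKey(ib)
  events <- list()
  add <- function(type, start, end, iso)
    events[[length(events) + 1L]] <<- data.frame(
      type = type, start = start, end = end, in_isoform = iso,
      stringsAsFactors = FALSE)

  if (identical(sort(ka), sort(kb)))
    return(data.frame(type = character(0), start = numeric(0),
                      end = numeric(0), in_isoform = character(0),
                      stringsAsFactors = FALSE))

  explained_a <- rep(FALSE, nrow(ia))
  explained_b <- rep(FALSE, nrow(ib))

  # intron retention: intron unique to one isoform contained in an exon of
  # the other (the retaining isoform is the one with the exon)
  for (i in seq_len(nrow(ia))) {
    if (ka[i] %in% kb) next
    if (any(eb$start <= ia$start[i] & eb$end >= ia$end[i])) {
      add("intron_retention", ia$start[i], ia$end[i], "b")
      explained_a[i] <- TRUE
    }
  }
  for (j in seq_len(nrow(ib))) {
    if (kb[j] %in% ka) next
    if (any(ea$start <= ib$start[j] & ea$end >= ib$end[j])) {
      add("intron_retention", ib$start[j], ib$end[j], "a")
      explained_b[j] <- TRUE
    }
  }

  # exon skipping: exon of one isoform strictly inside one intron of the
  # other, flanking introns sharing that intron's outer boundaries
  es_scan <- function(exons_in, introns_in, keys_in, introns_skip, skip_iso) {
    for (j in seq_len(nrow(introns_skip))) {
      ys <- introns_skip$start[j]; ye <- introns_skip$end[j]
      inside <- which(exons_in$start > ys & exons_in$end < ye)
      for (e in inside) {
        left <- paste(ys, exons_in$start[e] - 1)
        right <- paste(exons_in$end[e] + 1, ye)
        li <- match(left, keys_in)
        ri <- match(right, keys_in)
        if (!is.na(li) && !is.na(ri)) {
          add("exon_skipping", exons_in$start[e], exons_in$end[e], skip_iso)
          if (skip_iso == "b") {
            explained_b[j] <<- TRUE; explained_a[c(li, ri)] <<- TRUE
          } else {
            explained_a[j] <<- TRUE; explained_b[c(li, ri)] <<- TRUE
          }
        }
      }
    }
  }
  es_scan(ea, ia, ka, ib, "b")   # exon present in a, skipped in b
  es_scan(eb, ib, kb, ia, "a")

  # alternative donor/acceptor and residual complex pairs
  for (i in seq_len(nrow(ia))) {
    if (explained_a[i] || ka[i] %in% kb) next
    for (j in seq_len(nrow(ib))) {
      if (explained_b[j] || kb[j] %in% ka) next
      if (ib$start[j] > ia$end[i] || ib$end[j] < ia$start[i]) next  # no overlap
      same_donor <- ia$donor[i] == ib$donor[j]
      same_acceptor <- ia$acceptor[i] == ib$acceptor[j]
      lo <- min(ia$start[i], ib$start[j])
      hi <- max(ia$end[i], ib$end[j])
      if (same_donor && !same_acceptor) add("alt_acceptor", lo, hi, "pair")
      else if (same_acceptor && !same_donor) add("alt_donor", lo, hi, "pair")
      else add("other", lo, hi, "pair")
    }
  }

  if (length(events) == 0L)
    # structurally different intron chains with no overlapping difference
    add("other", min(ea$start, eb$start), max(ea$end, eb$end), "pair")
  out <- do.call(rbind, events)
  out <- out[order(out$type, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.CATEGORY_OF <- c(intron_retention = "IR", alt_acceptor = "AA",
                  alt_donor = "AD", exon_skipping = "ES")

#' Gene-level alternative-splicing call
#'
#' Takes the union of pairwise elementary events over all isoform pairs of
#' one gene.  Genes whose events are all of one elementary type are labeled
#' with that type (\code{IR}, \code{AA}, \code{AD}, \code{ES}); two or more
#' distinct types, or any unclassifiable structural difference, gives
#' \code{complex}; a single isoform or identical intron chains gives
#' \code{none}.
#'
#' @param isoforms Named list of exon tables (one per isoform).
#' @param strand Shared strand.
#' @return List: \code{category}, \code{events} (deduplicated event
#'   data.frame with \code{type}, \code{start}, \code{end}), and
#'   \code{n_isoforms}.
#' @export
classifyGeneAS <- function(isoforms, strand = "+") {
  n <- length(isoforms)
  if (n == 0L) stop("gene has no isoforms", call. = FALSE)
  all_events <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ev <- classifyPairEvents(isoforms[[i]], isoforms[[j]], strand)
        if (nrow(ev)) all_events[[length(all_events) + 1L]] <-
            ev[, c("type", "start", "end")]
      }
    }
  }
  events <- if (length(all_events)) unique(do.call(rbind, all_events)) else
    data.frame(type = character(0), start = numeric(0), end = numeric(0))
  rownames(events) <- NULL
  types <- unique(events$type)
  elementary <- setdiff(types, "other")
  category <-
    if (nrow(events) == 0L) "none"
    else if ("other" %in% types || length(elementary) > 1) "complex"
    else unname(.CATEGORY_OF[elementary])
  list(category = category, events = events, n_isoforms = n)
}

#' Proportions of alternative-splicing categories
#'
#' @param categories Character vector of gene-level categories (one per
#'   gene, values \code{IR}, \code{AA}, \code{AD}, \code{ES},
#'   \code{complex}, \code{none}).
#' @return List: \code{n_as_genes}, and \code{proportions} — the fraction of
#'   AS genes (category != none) per category, summing to 1 (empty when
#'   there are no AS genes).
#' @export
asSummary <- function(categories) {
  as_genes <- categories[categories != "none"]
  if (length(as_genes) == 0L)
    return(list(n_as_genes = 0L, proportions = numeric(0)))
  tab <- table(factor(as_genes, levels = c("IR", "AA", "AD", "ES", "complex")))
  tab <- tab[tab > 0]
  prop <- setNames(as.numeric(tab) / length(as_genes), names(tab))
  list(n_as_genes = length(as_genes), proportions = prop)
}

#' Classify alternative splicing for every multi-isoform gene of a GFF3
#'
#' @param gff GFF3 path or \code{GRanges} (see \code{\link{gffGeneModels}}).
#' @return data.frame: \code{gene_id}, \code{n_isoforms}, \code{category}.
#' @export
classifyGFFSplicing <- function(gff) {
  models <- if (is.list(gff) && !is(gff, "GRanges")) gff else gffGeneModels(gff)
  tx <- models$transcripts
  exons <- models$exons
  genes <- models$genes
  strand_of <- setNames(genes$strand, genes$gene_id)
  rows <- lapply(unique(tx$gene_id), function(g) {
    txs <- tx$tx_id[tx$gene_id == g]
    iso <- lapply(txs, function(t)
      exons[exons$tx_id == t, c("start", "end"), drop = FALSE])
    names(iso) <- txs
    call <- classifyGeneAS(iso, strand = strand_of[[g]])
    data.frame(gene_id = g, n_isoforms = call$n_isoforms,
               category = call$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene_id), , drop = FALSE]
}
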