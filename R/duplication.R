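# Tandem and segmental (collinear-block) duplication detection.
#
# Tandem rule: two genes of the same family on the same chromosome,
# separated by at most 5 intervening annotated genes (counted over ALL
# genes, not only kinases) and by strictly less than 100 kb between the
# nearest gene boundaries.  Segmental duplicates come from chains of
# homologous anchor pairs that are strictly monotone in gene rank on both
# chromosomes.

#' Call tandem duplicate pairs and arrays
#'
#' Emits a tandem event for every same-family gene pair on one chromosome
#' with at most \code{max_intervening} annotated genes between them and a
#' boundary-to-boundary separation strictly below \code{max_separation_bp}.
#' Arrays are the connected components of the pairwise tandem relation.
#'
#' @param genes data.frame of ALL annotated genes (not only kinases):
#'   columns \code{gene_id}, \code{chrom}, \code{start}, \code{end}.  Genes
#'   with missing coordinates are excluded with a warning.
#' @param families Named character vector mapping kinase gene ids to family
#'   labels; genes absent from it (or \code{"unclassified"}) are used only
#'   to count intervening genes.
#' @param max_intervening Maximum intervening gene count (inclusive,
#'   default 5).
#' @param max_separation_bp Strict upper bound on the boundary gap in bp
#'   (default 1e5).
#' @return List: \code{events} data.frame (\code{gene_a}, \code{gene_b} in
#'   canonical order, \code{chrom}, \code{family}, \code{intervening_genes},
#'   \code{separation_bp}), and \code{arrays} data.frame (\code{gene_id},
#'   \code{array_id}).
#' @export
callTandemDuplications <- function(genes, families, max_intervening = 5,
                                   max_separation_bp = 1e5) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% colnames(genes)))
  bad <- is.na(genes$start) | is.na(genes$end) | is.na(genes$chrom)
  if (any(bad)) {
    warning("excluded ", sum(bad), " gene(s) with missing coordinates",
            call. = FALSE)
    genes <- genes[!bad, , drop = FALSE]
  }
  fam <- families[match(genes$gene_id, names(families))]
  fam[fam == "unclassified"] <- NA
  ev <- list()
  for (chr in unique(genes$chrom)) {
    gi <- genes[genes$chrom == chr, , drop = FALSE]
    o <- order(gi$start, gi$end, gi$gene_id)
    gi <- gi[o, , drop = FALSE]
    fi <- fam[genes$chrom == chr][o]
    kin <- which(!is.na(fi))
    if (length(kin) < 2) next
    for (ii in seq_len(length(kin) - 1)) {
      for (jj in (ii + 1):length(kin)) {
        i <- kin[ii]; j <- kin[jj]
        if (fi[i] != fi[j]) next
        intervening <- j - i - 1L
        if (intervening > max_intervening) break  # further j only larger
        separation <- gi$start[j] - gi$end[i]
        if (separation >= max_separation_bp) next
        ev[[length(ev) + 1L]] <- data.frame(
          gene_a = min(gi$gene_id[i], gi$gene_id[j]),
          gene_b = max(gi$gene_id[i], gi$gene_id[j]),
          chrom = chr, family = fi[i],
          intervening_genes = intervening,
          separation_bp = separation,
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene_a = character(0), gene_b = character(0),
               chrom = character(0), family = character(0),
               intervening_genes = integer(0), separation_bp = numeric(0),
               stringsAsFactors = FALSE)
  events <- events[order(events$gene_a, events$gene_b), , drop = FALSE]
  rownames(events) <- NULL
  arrays <- .tandemArrays(events)
  list(events = events, arrays = arrays)
}

# Connected components of the tandem relation.
.tandemArrays <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(gene_id = character(0), array_id = integer(0),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(events[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  out <- data.frame(gene_id = names(comp$membership),
                    array_id = as.integer(comp$membership),
                    stringsAsFactors = FALSE)
  out <- out[order(out$array_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best monotone chain over anchors (rank_a strictly increasing; rank_b
# strictly increasing for orientation "same", strictly decreasing for
# "inverted"), with at most max_gap skipped ranks between consecutive
# anchors on either chromosome.  Returns indices of the best chain
# (longest; ties by smaller rank span) or integer(0).
.bestChain <- function(rank_a, rank_b, max_gap, inverted) {
  n <- length(rank_a)
  if (n == 0L) return(integer(0))
  rb <- if (inverted) -rank_b else rank_b
  o <- order(rank_a, rb)
  ra <- rank_a[o]; rbo <- rb[o]
  len <- rep(1L, n); span <- rep(0, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] >= ra[i] || rbo[j] >= rbo[i]) next
      if (ra[i] - ra[j] - 1L > max_gap) next
      if (abs(rbo[i] - rbo[j]) - 1L > max_gap) next
      cand_len <- len[j] + 1L
      cand_span <- span[j] + (ra[i] - ra[j]) + abs(rbo[i] - rbo[j])
      if (cand_len > len[i] ||
          (cand_len == len[i] && cand_span < span[i])) {
        len[i] <- cand_len; span[i] <- cand_span; prev[i] <- j
      }
    }
  }
  best <- which(len == max(len))
  best <- best[which.min(span[best])]
  chain <- integer(0)
  i <- best
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  o[chain]
}

#' Find collinear blocks by monotone anchor chaining
#'
#' Chains homologous anchor pairs into collinear blocks: maximal runs of
#' anchors whose gene ranks are strictly monotone on both chromosomes
#' (increasing/increasing, or increasing/decreasing for inverted blocks),
#' with at most \code{max_gap} skipped ranks between consecutive anchors
#' and at least \code{min_block} anchors per block.  Anchors are assigned
#' to at most one block, greedily by chain length (ties broken by the
#' smaller rank span).
#'
#' @param anchors data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{chrom_a}, \code{chrom_b}, \code{rank_a}, \code{rank_b} (gene
#'   order indices on the respective chromosomes).
#' @param min_block Minimum anchors per block (default 5).
#' @param max_gap Maximum skipped ranks between consecutive anchors
#'   (default 25).
#' @return data.frame of block anchors: \code{block_id}, \code{gene_a},
#'   \code{gene_b}, \code{chrom_a}, \code{chrom_b}, \code{rank_a},
#'   \code{rank_b}, \code{orientation}.
#' @export
findCollinearBlocks <- function(anchors, min_block = 5, max_gap = 25) {
  need <- c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")
  stopifnot(all(need %in% colnames(anchors)))
  out <- list()
  block_id <- 0L
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (k in unique(key)) {
    sub <- anchors[key == k, , drop = FALSE]
    repeat {
      if (nrow(sub) < min_block) break
      ch_s <- .bestChain(sub$rank_a, sub$rank_b, max_gap, inverted = FALSE)
      ch_i <- .bestChain(sub$rank_a, sub$rank_b, max_gap, inverted = TRUE)
      use_inv <- length(ch_i) > length(ch_s)
      ch <- if (use_inv) ch_i else ch_s
      if (length(ch) < min_block) break
      block_id <- block_id + 1L
      blk <- sub[ch, , drop = FALSE]
      blk$block_id <- block_id
      blk$orientation <- if (use_inv) "inverted" else "same"
      out[[length(out) + 1L]] <- blk
      sub <- sub[-ch, , drop = FALSE]
    }
  }
  if (length(out) == 0L)
    return(data.frame(block_id = integer(0), gene_a = character(0),
                      gene_b = character(0), chrom_a = character(0),
                      chrom_b = character(0), rank_a = integer(0),
                      rank_b = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[, c("block_id", need, "orientation")]
  res <- res[order(res$block_id, res$rank_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label each kinase by its duplication origin
#'
#' A gene is \code{tandem} if it appears in a tandem array, \code{segmental}
#' if it participates in at least one anchor pair inside a collinear block,
#' \code{both} if both, otherwise \code{none}.
#'
#' @param gene_ids Character vector of kinase gene ids to label.
#' @param tandem Output of \code{\link{callTandemDuplications}} (or its
#'   \code{arrays} component).
#' @param blocks Output of \code{\link{findCollinearBlocks}}.
#' @return Named character vector of labels.
#' @export
classifyDuplication <- function(gene_ids, tandem, blocks) {
  arr <- if (is.list(tandem) && !is.data.frame(tandem)) tandem$arrays else tandem
  in_tandem <- gene_ids %in% arr$gene_id
  in_block <- gene_ids %in% c(blocks$gene_a, blocks$gene_b)
  lab <- rep("none", length(gene_ids))
  lab[in_tandem] <- "tandem"
  lab[in_block] <- "segmental"
  lab[in_tandem & in_block] <- "both"
  setNames(lab, gene_ids)
}

#' Summarize duplication calls
#'
#' @param labels Named labels from \code{\link{classifyDuplication}}.
#' @param tandem Output of \code{\link{callTandemDuplications}}.
#' @param blocks Output of \code{\link{findCollinearBlocks}}.
#' @return List of pair/array/block/gene counts and the percentage of the
#'   kinome derived from each duplication mode.
#' @export
summarizeDuplication <- function(labels, tandem, blocks) {
  n <- length(labels)
  n_tandem_genes <- sum(labels %in% c("tandem", "both"))
  n_seg_genes <- sum(labels %in% c("segmental", "both"))
  list(
    n_genes = n,
    n_tandem_pairs = nrow(tandem$events),
    n_tandem_arrays = length(unique(tandem$arrays$array_id)),
    n_tandem_genes = n_tandem_genes,
    n_blocks = length(unique(blocks$block_id)),
    n_anchor_pairs = nrow(blocks),
    n_segmental_genes = n_seg_genes,
    tandem_gene_pct = if (n) round(100 * n_tandem_genes / n, 1) else NA_real_,
    segmental_gene_pct = if (n) round(100 * n_seg_genes / n, 1) else NA_real_
  )
}
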