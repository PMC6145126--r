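# Isoform fixtures exhibiting prescribed alternative-splicing events.

.AS_TYPES <- c("IR", "AA", "AD", "ES", "complex")

#' Generate a gene with isoforms exhibiting prescribed splicing events
#'
#' Builds a five-exon canonical transcript and, for every requested event
#' type, one variant isoform that differs from the canonical isoform by
#' exactly that event: \code{IR} retains the second intron, \code{AA}
#' shifts the acceptor of the second intron, \code{AD} shifts its donor,
#' \code{ES} skips the third exon, and \code{complex} replaces the second
#' intron by an overlapping intron differing at both boundaries.  An empty
#' event list yields two identical isoforms.  Boundary shifts are
#' strand-resolved (donor = 5' end of the intron).
#'
#' @param events Character vector drawn from \code{IR}, \code{AA},
#'   \code{AD}, \code{ES}, \code{complex} (possibly empty).
#' @param gene_id Gene identifier.
#' @param strand \code{"+"} or \code{"-"}.
#' @param offset Genomic offset added to all coordinates.
#' @return List: \code{gene_id}, \code{strand}, \code{isoforms} (named list
#'   of exon data.frames, first one canonical), \code{events_requested}.
#' @examples
#' g <- simIsoforms("IR")
#' classifyGeneAS(g$isoforms, g$strand)$category
#' @export
simIsoforms <- function(events = character(0), gene_id = "geneAS",
                        strand = "+", offset = 0) {
  events <- as.character(events)
  unknown <- setdiff(events, .AS_TYPES)
  if (length(unknown) > 0)
    stop("unknown AS event type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  strand <- match.arg(strand, c("+", "-"))
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE) + offset
    data.frame(start = m[, 1], end = m[, 2])
  }
  canonical <- ex(101, 200, 301, 400, 501, 600, 701, 800, 901, 1000)
  # second intron of the canonical model is [401, 500]
  variant <- list(
    IR = ex(101, 200, 301, 600, 701, 800, 901, 1000),
    ES = ex(101, 200, 301, 400, 701, 800, 901, 1000),
    # acceptor = 3' end of the intron: end on "+", start on "-"
    AA = if (strand == "+") ex(101, 200, 301, 400, 489, 600, 701, 800, 901, 1000)
         else               ex(101, 200, 301, 412, 501, 600, 701, 800, 901, 1000),
    AD = if (strand == "+") ex(101, 200, 301, 412, 501, 600, 701, 800, 901, 1000)
         else               ex(101, 200, 301, 400, 489, 600, 701, 800, 901, 1000),
    complex = ex(101, 200, 301, 420, 521, 600, 701, 800, 901, 1000)
  )
  isoforms <- list(canonical)
  if (length(events) == 0L) {
    isoforms <- c(isoforms, list(canonical))
  } else {
    for (e in events) isoforms <- c(isoforms, list(variant[[e]]))
  }
  names(isoforms) <- paste0(gene_id, ".", seq_along(isoforms))
  list(gene_id = gene_id, strand = strand, isoforms = isoforms,
       events_requested = events)
}

#' Simulate a cohort of genes with planted AS categories
#'
#' @param category_counts Named integer vector over \code{IR}, \code{AA},
#'   \code{AD}, \code{ES}, \code{complex}, \code{none}: number of genes to
#'   plant per gene-level category.
#' @param seed Integer seed (strands are drawn at random).
#' @return List: \code{genes} (list of \code{\link{simIsoforms}} results),
#'   \code{truth} (data.frame \code{gene_id}, \code{category}).
#' @export
simASCohort <- function(category_counts, seed = 1) {
  stopifnot(all(names(category_counts) %in% c(.AS_TYPES, "none")))
  withSeed(seed, {
    genes <- list()
    truth <- list()
    i <- 0L
    for (cat in names(category_counts)) {
      for (rep in seq_len(category_counts[[cat]])) {
        i <- i + 1L
        gid <- sprintf("asgene%04d", i)
        strand <- sample(c("+", "-"), 1)
        ev <- switch(cat,
                     none = character(0),
                     complex = c("AA", "ES"),
                     cat)
        genes[[gid]] <- simIsoforms(ev, gene_id = gid, strand = strand)
        truth[[gid]] <- data.frame(gene_id = gid, category = cat,
                                   stringsAsFactors = FALSE)
      }
    }
    list(genes = genes, truth = do.call(rbind, truth))
  })
}
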