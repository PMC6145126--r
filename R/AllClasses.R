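#' KinaseCatalog: a classified kinase gene set
#'
#' Container for the per-gene results of kinase identification and
#' classification: family and group assignment, kinase-domain multiplicity,
#' intron count of the representative (longest-CDS) transcript, and genomic
#' location.  Built by \code{\link{buildKinaseCatalog}}; summarized by
#' \code{\link{summarizeCatalog}}.
#'
#' @slot records A \code{\link[S4Vectors]{DataFrame}} with one row per kinase
#'   gene and columns \code{gene_id}, \code{protein_id}, \code{family},
#'   \code{group}, \code{n_kinase_domains}, \code{intron_count},
#'   \code{chrom}, \code{is_scaffold}, \code{start}, \code{end},
#'   \code{strand}, \code{family_tie}, \code{score_margin}.
#' @slot params List of the filter parameters the catalog was built with.
#' @exportClass KinaseCatalog
setClass("KinaseCatalog",
         representation(records = "DataFrame", params = "list"))

setValidity("KinaseCatalog", function(object) {
  rec <- object@records
  need <- c("gene_id", "protein_id", "family", "group", "n_kinase_domains",
            "intron_count", "chrom", "is_scaffold", "start", "end", "strand")
  miss <- setdiff(need, colnames(rec))
  if (length(miss) > 0)
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(rec) > 0) {
    if (any(rec$n_kinase_domains < 1))
      return("every cataloged kinase must have >= 1 kinase domain")
    if (any(rec$intron_count < 0))
      return("negative intron counts")
    bad <- rec$family == "unclassified" & rec$group != "unclassified"
    if (any(bad))
      return("unclassified family implies unclassified group")
    if (anyDuplicated(rec$gene_id))
      return("duplicate gene ids")
  }
  TRUE
})

#' @describeIn KinaseCatalog Number of kinase genes in the catalog.
#' @param x A \code{KinaseCatalog}.
#' @export
setMethod("length", "KinaseCatalog", function(x) nrow(x@records))

setMethod("show", "KinaseCatalog", function(object) {
  rec <- object@records
  cat("KinaseCatalog with", nrow(rec), "kinase genes\n")
  if (nrow(rec) > 0) {
    cat("  families:", length(unique(rec$family[rec$family != "unclassified"])),
        " groups:", length(unique(rec$group[rec$group != "unclassified"])),
        " unclassified:", sum(rec$family == "unclassified"), "\n")
    cat("  multi-domain:", sum(rec$n_kinase_domains > 1),
        " on scaffolds:", sum(rec$is_scaffold), "\n")
  }
  invisible(object)
})

#' Extract the per-gene records of a KinaseCatalog
#'
#' @param x A \code{KinaseCatalog}.
#' @return A base \code{data.frame}, one row per kinase gene.
#' @export
catalogRecords <- function(x) {
  stopifnot(is(x, "KinaseCatalog"))
  as.data.frame(x@records)
}

#' CoexpressionNetwork: significant Pearson coexpression edges
#'
#' Holds the edge list of a thresholded Pearson correlation network
#' together with the thresholds it was built under.  Built by
#' \code{\link{buildCoexpressionNetwork}}.
#'
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{r}, \code{p}, \code{sign} (canonical order \code{node_a <
#'   node_b}).
#' @slot params List: \code{min_abs_pcc}, \code{alpha}, \code{n_samples}.
#' @slot dropped Character vector of constant-profile nodes excluded before
#'   correlation.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(edges = "data.frame", params = "list",
                        dropped = "character"))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  need <- c("node_a", "node_b", "r", "p", "sign")
  if (!all(need %in% colnames(e)))
    return("edge columns must be node_a, node_b, r, p, sign")
  if (nrow(e) > 0) {
    if (any(e$node_a >= e$node_b))
      return("edges must be stored with node_a < node_b")
    if (any(abs(e$r) > 1) || any(e$p < 0 | e$p > 1))
      return("r must lie in [-1,1] and p in [0,1]")
    if (!all(e$sign == ifelse(e$r > 0, "positive", "negative")))
      return("edge sign must match the sign of r")
  }
  TRUE
})

setMethod("show", "CoexpressionNetwork", function(object) {
  e <- object@edges
  nodes <- unique(c(e$node_a, e$node_b))
  cat("CoexpressionNetwork:", length(nodes), "nodes,", nrow(e), "edges",
      sprintf("(|r| > %g, p < %g, n = %d)\n",
              object@params$min_abs_pcc, object@params$alpha,
              object@params$n_samples))
  if (length(object@dropped) > 0)
    cat("  constant profiles dropped:", length(object@dropped), "\n")
  invisible(object)
})

#' Extract the edge list of a CoexpressionNetwork
#'
#' @param x A \code{CoexpressionNetwork}.
#' @return data.frame of edges (\code{node_a}, \code{node_b}, \code{r},
#'   \code{p}, \code{sign}).
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork"))
  x@edges
}

#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL
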