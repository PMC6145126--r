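# Kinase identification and classification from profile-HMM domain hits.
#
# A protein is called a kinase when at least one catalytic-model hit passes
# both filters: per-domain E-value strictly below the cutoff (default 1e-5)
# and alignment covering at least half of the profile model (inclusive at
# exactly 50%).  Family/group labels come from the best-scoring accepted
# family-model hit.

.HIT_COLUMNS <- c("protein_id", "model_name", "model_length", "seq_evalue",
                  "dom_evalue", "bit_score", "hmm_from", "hmm_to",
                  "ali_from", "ali_to")
.NUM_COLUMNS <- .HIT_COLUMNS[3:10]

#' Default catalytic kinase-domain model names
#'
#' The Pfam kinase-clan models used to call a protein a kinase.
#' @return Character vector of model names.
#' @export
catalyticModels <- function() c("Pkinase", "Pkinase_Tyr")

#' Read a per-domain profile-HMM hit table
#'
#' Parses the whitespace-delimited per-domain hit dialect written by common
#' profile-HMM search tools (and by \code{\link{simKinomeGenome}}): one row
#' per domain alignment with columns target protein, query model, model
#' length, full-sequence E-value, per-domain independent E-value, bit score,
#' model (hmm) from/to and protein (ali) from/to coordinates, all 1-based
#' inclusive.  Lines starting with \code{#} and blank lines are skipped.
#' Malformed rows (wrong field count, non-numeric values, or coordinate
#' invariant violations such as \code{hmm_to > model_length}) are dropped
#' with a warning that names the offending line numbers.
#'
#' @param path Path to the hit table (or a connection).
#' @return data.frame with columns \code{protein_id}, \code{model_name},
#'   \code{model_length}, \code{seq_evalue}, \code{dom_evalue},
#'   \code{bit_score}, \code{hmm_from}, \code{hmm_to}, \code{ali_from},
#'   \code{ali_to}.
#' @export
readDomainHits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  empty <- data.frame(matrix(nrow = 0, ncol = length(.HIT_COLUMNS),
                             dimnames = list(NULL, .HIT_COLUMNS)))
  empty[.NUM_COLUMNS] <- lapply(empty[.NUM_COLUMNS], as.numeric)
  if (length(rows) == 0L) return(empty)
  nf <- lengths(rows)
  if (all(nf < length(.HIT_COLUMNS))) {
    missing_from <- max(nf) + 1L
    stop("hit table is missing required column(s): ",
         paste(.HIT_COLUMNS[missing_from:length(.HIT_COLUMNS)],
               collapse = ", "), call. = FALSE)
  }
  bad <- integer(0)
  parse_row <- function(i) {
    f <- rows[[i]]
    if (length(f) < length(.HIT_COLUMNS)) return(NULL)
    num <- suppressWarnings(as.numeric(f[3:10]))
    if (any(is.na(num))) return(NULL)
    # num: 1 model_length, 2 seq_evalue, 3 dom_evalue, 4 bit_score,
    #      5 hmm_from, 6 hmm_to, 7 ali_from, 8 ali_to
    if (num[2] < 0 || num[3] < 0) return(NULL)              # E-values >= 0
    if (!(num[5] <= num[6] && num[6] <= num[1])) return(NULL)
    if (!(num[7] <= num[8])) return(NULL)
    if (num[1] <= 0 || num[5] < 1 || num[7] < 1) return(NULL)
    data.frame(protein_id = f[1], model_name = f[2],
               model_length = num[1], seq_evalue = num[2],
               dom_evalue = num[3], bit_score = num[4],
               hmm_from = num[5], hmm_to = num[6],
               ali_from = num[7], ali_to = num[8],
               stringsAsFactors = FALSE)
  }
  parsed <- lapply(seq_along(rows), parse_row)
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning("dropped ", sum(!ok), " malformed hit row(s) at line(s): ",
            paste(head(lineno[!ok], 10), collapse = ", "), call. = FALSE)
  if (!any(ok)) return(empty)
  out <- do.call(rbind, parsed[ok])
  rownames(out) <- NULL
  out
}

#' Filter domain hits by E-value and model coverage
#'
#' Keeps hits whose E-value is strictly below \code{evalue_max} and whose
#' alignment covers at least \code{min_model_coverage} of the profile model,
#' computed on model coordinates as \code{(hmm_to - hmm_from + 1) /
#' model_length} (inclusive at the threshold).  By default the per-domain
#' independent E-value is used; set \code{evalue_on = "sequence"} to filter
#' on the full-sequence E-value instead.
#'
#' @param hits data.frame from \code{\link{readDomainHits}}.
#' @param evalue_max Strict upper bound on the E-value (default \code{1e-5}).
#' @param min_model_coverage Minimum model coverage in (0, 1] (default 0.5).
#' @param evalue_on Which E-value column the cutoff applies to.
#' @return The accepted subset of \code{hits}.
#' @examples
#' h <- data.frame(protein_id = "p1", model_name = "Pkinase",
#'                 model_length = 260, seq_evalue = 1e-12,
#'                 dom_evalue = 1e-10, bit_score = 200,
#'                 hmm_from = 1, hmm_to = 130, ali_from = 5, ali_to = 140)
#' nrow(filterKinaseHits(h))  # coverage exactly 0.5 is accepted
#' @export
filterKinaseHits <- function(hits, evalue_max = 1e-5, min_model_coverage = 0.5,
                             evalue_on = c("domain", "sequence")) {
  evalue_on <- match.arg(evalue_on)
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    stop("'evalue_max' must be > 0", call. = FALSE)
  if (!is.numeric(min_model_coverage) || min_model_coverage <= 0 ||
      min_model_coverage > 1)
    stop("'min_model_coverage' must be in (0, 1]", call. = FALSE)
  if (nrow(hits) == 0L) return(hits)
  ev <- if (evalue_on == "domain") hits$dom_evalue else hits$seq_evalue
  coverage <- (hits$hmm_to - hits$hmm_from + 1) / hits$model_length
  hits[ev < evalue_max & coverage >= min_model_coverage, , drop = FALSE]
}

#' Assign a kinase family and group from family-model bit scores
#'
#' Picks the family whose accepted family-model hit has the highest bit
#' score.  The group is the family-name prefix before the first underscore
#' (with the \code{RLK-Pelle} prefix reported as group \code{RLK}).  With no
#' accepted family hit the protein is \code{"unclassified"} in both fields.
#' Exact score ties are broken lexicographically and flagged, and the score
#' margin between the best and second-best family is reported so ambiguous
#' assignments are visible.
#'
#' @param family_scores Named numeric vector: best bit score per candidate
#'   family for one protein (may be empty).
#' @return List with \code{family}, \code{group}, \code{tie} (logical) and
#'   \code{margin} (best minus runner-up score; \code{Inf} with a single
#'   candidate, \code{NA} when unclassified).
#' @export
assignFamily <- function(family_scores) {
  if (length(family_scores) == 0L || all(is.na(family_scores)))
    return(list(family = "unclassified", group = "unclassified",
                tie = FALSE, margin = NA_real_))
  fam <- names(family_scores)
  if (is.null(fam)) stop("'family_scores' must be named", call. = FALSE)
  # collapse duplicate family names to their best score
  best_by_fam <- tapply(family_scores, fam, max)
  sc <- as.numeric(best_by_fam)
  nm <- names(best_by_fam)
  top <- max(sc)
  winners <- sort(nm[sc == top])
  family <- winners[1]
  tie <- length(winners) > 1
  margin <- if (length(sc) == 1L) Inf else {
    if (tie) 0 else top - max(sc[nm != family])
  }
  list(family = family, group = familyGroup(family), tie = tie,
       margin = margin)
}

#' Group label of a kinase family name
#'
#' @param family Character vector of family names.
#' @return Group labels: the prefix before the first underscore, with
#'   \code{RLK-Pelle} collapsed to \code{RLK}; \code{"unclassified"} passes
#'   through.
#' @export
familyGroup <- function(family) {
  g <- sub("_.*$", "", family)
  g[g == "RLK-Pelle"] <- "RLK"
  g[family == "unclassified"] <- "unclassified"
  g
}

#' Count non-overlapping kinase domains in one protein
#'
#' Counts kinase-domain copies from accepted catalytic hits, merging hits
#' whose protein-coordinate overlap exceeds 50% of the shorter interval
#' (transitively), so that split alignments of one domain are not counted
#' twice.
#'
#' @param hits Accepted catalytic hits of one protein (needs \code{ali_from},
#'   \code{ali_to}).
#' @return Integer domain count (0 for an empty hit set).
#' @export
countKinaseDomains <- function(hits) {
  n <- nrow(hits)
  if (is.null(n) || n == 0L) return(0L)
  if (n == 1L) return(1L)
  from <- hits$ali_from
  to <- hits$ali_to
  merged <- seq_len(n)                      # union-find over hit indices
  find <- function(i) { while (merged[i] != i) i <- merged[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ov <- min(to[i], to[j]) - max(from[i], from[j]) + 1
      shorter <- min(to[i] - from[i] + 1, to[j] - from[j] + 1)
      if (ov > 0.5 * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) merged[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Intron count of a transcript model
#'
#' @param exons data.frame (or matrix) of exon \code{start}, \code{end}
#'   positions of one transcript.
#' @return Number of introns, i.e. number of exons minus one.
#' @export
countIntrons <- function(exons) {
  n <- if (is.data.frame(exons) || is.matrix(exons)) nrow(exons)
       else length(exons)
  if (is.null(n) || n == 0L)
    stop("transcript has no exons", call. = FALSE)
  as.integer(n - 1L)
}

# ---- GFF helpers -----------------------------------------------------------

.asChar1 <- function(x) {
  # Parent comes back from rtracklayer as a CharacterList
  if (is(x, "List") || is.list(x))
    vapply(x, function(v) if (length(v)) as.character(v[1]) else NA_character_,
           character(1))
  else as.character(x)
}

#' Tabulate gene models from an imported GFF3
#'
#' Flattens a \code{GRanges} imported with
#' \code{\link[rtracklayer]{import}} (gene -> mRNA -> exon/CDS hierarchy)
#' into per-gene and per-transcript tables used by the catalog and splicing
#' code.
#'
#' @param gff A \code{GRanges} with \code{type}, \code{ID}, \code{Parent}
#'   metadata columns, or a path to a GFF3 file.
#' @return List: \code{genes} (gene_id, chrom, start, end, strand),
#'   \code{transcripts} (tx_id, gene_id, n_exons, cds_length),
#'   \code{exons} (tx_id, start, end).
#' @export
gffGeneModels <- function(gff) {
  if (is.character(gff)) gff <- rtracklayer::import(gff, format = "gff3")
  type <- as.character(gff$type)
  id <- .asChar1(gff$ID)
  parent <- .asChar1(gff$Parent)
  gi <- type == "gene"
  genes <- data.frame(gene_id = id[gi],
                      chrom = as.character(GenomicRanges::seqnames(gff)[gi]),
                      start = GenomicRanges::start(gff)[gi],
                      end = GenomicRanges::end(gff)[gi],
                      strand = as.character(GenomicRanges::strand(gff)[gi]),
                      stringsAsFactors = FALSE)
  ti <- type %in% c("mRNA", "transcript")
  tx <- data.frame(tx_id = id[ti], gene_id = parent[ti],
                   stringsAsFactors = FALSE)
  ei <- type == "exon"
  exons <- data.frame(tx_id = parent[ei],
                      start = GenomicRanges::start(gff)[ei],
                      end = GenomicRanges::end(gff)[ei],
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  ci <- type == "CDS"
  cds_w <- GenomicRanges::width(gff)[ci]
  cds_len <- tapply(cds_w, parent[ci], sum)
  tx$n_exons <- as.integer(table(exons$tx_id)[tx$tx_id])
  tx$n_exons[is.na(tx$n_exons)] <- 0L
  tx$cds_length <- as.numeric(cds_len[tx$tx_id])
  tx$cds_length[is.na(tx$cds_length)] <- 0
  list(genes = genes, transcripts = tx, exons = exons)
}

# Representative (longest-CDS) transcript per gene; ties broken by tx_id so
# the choice is reproducible.
.representativeTx <- function(models) {
  tx <- models$transcripts
  tx <- tx[order(tx$gene_id, -tx$cds_length, tx$tx_id), , drop = FALSE]
  tx[!duplicated(tx$gene_id), , drop = FALSE]
}

#' Build a kinase catalog from domain hits and gene models
#'
#' Runs the identification filter on a domain-hit table, classifies each
#' identified kinase into a family and group from its family-model hits,
#' counts kinase-domain copies and introns (on the representative,
#' longest-CDS transcript), and attaches genomic coordinates.  Proteins are
#' matched to gene models by transcript ID.
#'
#' @param hits data.frame from \code{\link{readDomainHits}}.
#' @param gff \code{GRanges} or GFF3 path (see \code{\link{gffGeneModels}}).
#' @param evalue_max,min_model_coverage,evalue_on Passed to
#'   \code{\link{filterKinaseHits}}.
#' @param catalytic Model names treated as catalytic kinase domains.
#' @return A \code{\linkS4class{KinaseCatalog}}.
#' @export
buildKinaseCatalog <- function(hits, gff, evalue_max = 1e-5,
                               min_model_coverage = 0.5,
                               evalue_on = "domain",
                               catalytic = catalyticModels()) {
  models <- if (is.list(gff) && !is(gff, "GRanges")) gff else gffGeneModels(gff)
  acc <- filterKinaseHits(hits, evalue_max, min_model_coverage, evalue_on)
  cat_hits <- acc[acc$model_name %in% catalytic, , drop = FALSE]
  fam_hits <- acc[!(acc$model_name %in% catalytic), , drop = FALSE]
  kin_prot <- unique(cat_hits$protein_id)

  tx <- models$transcripts
  known <- kin_prot %in% tx$tx_id
  if (any(!known))
    warning("no gene model for ", sum(!known), " kinase protein(s); skipped",
            call. = FALSE)
  kin_prot <- kin_prot[known]
  rep_tx <- .representativeTx(models)
  gene_of <- setNames(tx$gene_id, tx$tx_id)
  genes <- models$genes
  rownames(genes) <- genes$gene_id
  exn <- setNames(rep_tx$n_exons, rep_tx$gene_id)

  rows <- lapply(kin_prot, function(p) {
    g <- gene_of[[p]]
    fh <- fam_hits[fam_hits$protein_id == p, , drop = FALSE]
    asg <- assignFamily(setNames(fh$bit_score, fh$model_name))
    nd <- countKinaseDomains(cat_hits[cat_hits$protein_id == p, , drop = FALSE])
    gi <- genes[g, ]
    data.frame(gene_id = g, protein_id = p,
               family = asg$family, group = asg$group,
               n_kinase_domains = nd,
               intron_count = max(exn[[g]] - 1L, 0L),
               chrom = gi$chrom,
               is_scaffold = grepl("scaffold", gi$chrom, ignore.case = TRUE),
               start = gi$start, end = gi$end, strand = gi$strand,
               family_tie = asg$tie, score_margin = asg$margin,
               stringsAsFactors = FALSE)
  })
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), protein_id = character(0),
               family = character(0), group = character(0),
               n_kinase_domains = integer(0), intron_count = integer(0),
               chrom = character(0), is_scaffold = logical(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               family_tie = logical(0), score_margin = numeric(0),
               stringsAsFactors = FALSE)
  rec <- rec[order(rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  new("KinaseCatalog", records = DataFrame(rec),
      params = list(evalue_max = evalue_max,
                    min_model_coverage = min_model_coverage,
                    evalue_on = evalue_on, catalytic = catalytic))
}

#' Summarize a kinase catalog
#'
#' Per-family, per-group and per-chromosome member counts, a kinase-domain
#' multiplicity histogram, and derived proportions.  Genes on scaffolds are
#' tallied separately from chromosomes.
#'
#' @param catalog A \code{\linkS4class{KinaseCatalog}} or its record
#'   data.frame.
#' @param genome_size Optional total number of protein-coding genes in the
#'   genome, used for the kinome fraction.
#' @return List with \code{n_kinases}, \code{n_classified},
#'   \code{n_unclassified}, \code{n_families}, \code{n_groups},
#'   \code{family_counts}, \code{group_counts}, \code{chromosome_counts},
#'   \code{n_scaffold_genes}, \code{n_chromosomal_genes},
#'   \code{domain_multiplicity} (table of domain counts),
#'   \code{n_multidomain}, \code{largest_group_pct} and (when
#'   \code{genome_size} is given) \code{kinome_fraction_pct}.
#' @export
summarizeCatalog <- function(catalog, genome_size = NULL) {
  rec <- if (is(catalog, "KinaseCatalog")) catalogRecords(catalog) else catalog
  n <- nrow(rec)
  cls <- rec$family != "unclassified"
  fam <- sort(table(rec$family[cls]), decreasing = TRUE)
  grp <- sort(table(rec$group[cls]), decreasing = TRUE)
  chrom <- table(rec$chrom[!rec$is_scaffold])
  mult <- table(rec$n_kinase_domains)
  out <- list(
    n_kinases = n,
    n_classified = sum(cls),
    n_unclassified = sum(!cls),
    n_families = length(fam),
    n_groups = length(grp),
    family_counts = fam,
    group_counts = grp,
    chromosome_counts = chrom,
    n_scaffold_genes = sum(rec$is_scaffold),
    n_chromosomal_genes = sum(!rec$is_scaffold),
    domain_multiplicity = mult,
    n_multidomain = sum(rec$n_kinase_domains > 1),
    largest_group_pct = if (length(grp)) round(100 * max(grp) / n, 1) else NA_real_
  )
  if (!is.null(genome_size))
    out$kinome_fraction_pct <- round(100 * n / genome_size, 1)
  out
}
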