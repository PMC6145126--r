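# End-to-end orchestration: catalog -> duplication -> kaks,
# catalog -> expression -> network, splicing independent.  Every stage is a
# pure function of its inputs plus the config and seed, so a rerun with the
# same config reproduces the outputs byte for byte.

#' Read a plain-text pipeline configuration
#'
#' Parses \code{key = value} lines (\code{#} comments and blank lines
#' ignored) into a named list; numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lengths(kv) != 3
  if (any(bad))
    stop("malformed config line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  out <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 2)
  out
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the kinome analysis pipeline
#'
#' Executes the enabled stages in dependency order on file inputs (or
#' in-memory equivalents), writes every stage's tables to \code{out_dir},
#' and returns a run report whose counts equal the row counts of the
#' written files.
#'
#' @param hits Domain-hit table path (or data.frame).
#' @param gff GFF3 path (or \code{GRanges} / \code{\link{gffGeneModels}}
#'   list).
#' @param cds CDS FASTA path (or named \code{DNAStringSet}); needed for the
#'   kaks stage.
#' @param anchors Anchor-pair TSV path (or data.frame); needed for the
#'   duplication stage.
#' @param expression Expression-matrix TSV path (gene rows, sample columns;
#'   or matrix); needed for the expression and network stages.
#' @param out_dir Output directory.
#' @param stages Character subset of \code{c("catalog", "duplication",
#'   "kaks", "splicing", "expression", "network")}.
#' @param evalue_max,min_model_coverage Identification filter thresholds.
#' @param max_intervening,max_separation_bp Tandem rule thresholds.
#' @param min_block,max_gap Collinear-block chaining parameters.
#' @param ks_bin_width Ks histogram bin width.
#' @param fpkm_threshold Low-expression filter threshold.
#' @param k,n_restarts k-means parameters.
#' @param min_abs_pcc,alpha Network thresholds.
#' @param cluster_on_log Cluster log2(FPKM+1) profiles (default) rather
#'   than raw FPKM.
#' @param seed Integer seed (k-means restarts).
#' @return The run report (list), invisibly also written as
#'   \code{report.json} in \code{out_dir}.
#' @export
runKinomePipeline <- function(hits, gff, cds = NULL, anchors = NULL,
                              expression = NULL, out_dir = tempfile("kinome"),
                              stages = c("catalog", "duplication", "kaks",
                                         "splicing", "expression", "network"),
                              evalue_max = 1e-5, min_model_coverage = 0.5,
                              max_intervening = 5, max_separation_bp = 1e5,
                              min_block = 5, max_gap = 25,
                              ks_bin_width = 0.1, fpkm_threshold = 10,
                              k = 10, n_restarts = 10,
                              min_abs_pcc = 0.8, alpha = 0.01,
                              cluster_on_log = TRUE, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  report <- list(stages = stages,
                 params = list(evalue_max = evalue_max,
                               min_model_coverage = min_model_coverage,
                               max_intervening = max_intervening,
                               max_separation_bp = max_separation_bp,
                               min_block = min_block, max_gap = max_gap,
                               ks_bin_width = ks_bin_width,
                               fpkm_threshold = fpkm_threshold,
                               k = k, n_restarts = n_restarts,
                               min_abs_pcc = min_abs_pcc, alpha = alpha,
                               cluster_on_log = cluster_on_log, seed = seed))

  if (is.character(hits)) hits <- readDomainHits(hits)
  models <- if (is.list(gff) && !is(gff, "GRanges")) gff else gffGeneModels(gff)

  catalog <- NULL
  if ("catalog" %in% stages) {
    catalog <- tryCatch(
      buildKinaseCatalog(hits, models, evalue_max, min_model_coverage),
      error = function(e) fail("catalog", e))
    rec <- catalogRecords(catalog)
    .writeTSV(rec, file.path(out_dir, "catalog.tsv"))
    s <- summarizeCatalog(catalog)
    .writeTSV(data.frame(family = names(s$family_counts),
                         n = as.integer(s$family_counts)),
              file.path(out_dir, "family_counts.tsv"))
    report$catalog <- list(n_kinases = s$n_kinases,
                           n_families = s$n_families,
                           n_groups = s$n_groups,
                           n_unclassified = s$n_unclassified,
                           n_multidomain = s$n_multidomain,
                           n_scaffold_genes = s$n_scaffold_genes)
  }

  tandem <- NULL; blocks <- NULL
  if ("duplication" %in% stages) {
    if (is.null(catalog)) stop("duplication stage requires catalog stage",
                               call. = FALSE)
    rec <- catalogRecords(catalog)
    fams <- setNames(rec$family, rec$gene_id)
    tandem <- tryCatch(
      callTandemDuplications(models$genes, fams, max_intervening,
                             max_separation_bp),
      error = function(e) fail("duplication", e))
    if (is.character(anchors))
      anchors <- read.table(anchors, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    blocks <- if (!is.null(anchors) && nrow(anchors) > 0)
      findCollinearBlocks(anchors, min_block, max_gap)
    else findCollinearBlocks(data.frame(gene_a = character(0),
                                        gene_b = character(0),
                                        chrom_a = character(0),
                                        chrom_b = character(0),
                                        rank_a = integer(0),
                                        rank_b = integer(0)))
    labels <- classifyDuplication(rec$gene_id, tandem, blocks)
    .writeTSV(tandem$events, file.path(out_dir, "tandem_events.tsv"))
    .writeTSV(blocks, file.path(out_dir, "collinear_blocks.tsv"))
    .writeTSV(data.frame(gene_id = names(labels), origin = labels),
              file.path(out_dir, "duplication_origin.tsv"))
    report$duplication <- summarizeDuplication(labels, tandem, blocks)
  }

  if ("kaks" %in% stages) {
    if (is.null(tandem)) stop("kaks stage requires duplication stage",
                              call. = FALSE)
    if (is.null(cds)) stop("kaks stage requires CDS sequences", call. = FALSE)
    if (is.character(cds)) cds <- Biostrings::readDNAStringSet(cds)
    rec <- catalogRecords(catalog)
    tx_of <- setNames(rec$protein_id, rec$gene_id)
    pair_sets <- list(tandem = tandem$events[, c("gene_a", "gene_b")])
    if (nrow(blocks) > 0)
      pair_sets$segmental <- unique(blocks[, c("gene_a", "gene_b")])
    kk <- lapply(names(pair_sets), function(kind) {
      p <- pair_sets[[kind]]
      if (nrow(p) == 0) return(NULL)
      p$gene_a <- unname(tx_of[p$gene_a]); p$gene_b <- unname(tx_of[p$gene_b])
      p <- p[!is.na(p$gene_a) & !is.na(p$gene_b), , drop = FALSE]
      if (nrow(p) == 0) return(NULL)
      res <- tryCatch(kaKsTable(p, cds), error = function(e) fail("kaks", e))
      res$kind <- kind
      res
    })
    kk <- do.call(rbind, kk)
    if (is.null(kk))
      kk <- data.frame(gene_a = character(0), gene_b = character(0),
                       Ka = numeric(0), Ks = numeric(0), ratio = numeric(0),
                       selection = character(0), kind = character(0))
    .writeTSV(kk, file.path(out_dir, "kaks.tsv"))
    h <- ksHistogram(kk$Ks, ks_bin_width)
    .writeTSV(h$bins, file.path(out_dir, "ks_histogram.tsv"))
    report$kaks <- list(n_pairs = nrow(kk),
                        selection = as.list(table(kk$selection)),
                        ks_peak = h$peak)
  }

  if ("splicing" %in% stages) {
    as_calls <- tryCatch(classifyGFFSplicing(models),
                         error = function(e) fail("splicing", e))
    .writeTSV(as_calls, file.path(out_dir, "splicing.tsv"))
    s <- asSummary(as_calls$category)
    report$splicing <- list(n_genes = nrow(as_calls),
                            n_as_genes = s$n_as_genes,
                            proportions = as.list(s$proportions))
  }

  clus <- NULL; log_mat <- NULL
  if ("expression" %in% stages) {
    if (is.null(expression)) stop("expression stage requires a matrix",
                                  call. = FALSE)
    if (is.character(expression))
      expression <- as.matrix(read.table(expression, header = TRUE,
                                         sep = "\t", row.names = 1,
                                         check.names = FALSE))
    fl <- tryCatch(filterLowExpression(expression, fpkm_threshold),
                   error = function(e) fail("expression", e))
    log_mat <- logTransform(fl$retained)
    cl_in <- if (cluster_on_log) log_mat else fl$retained
    clus <- kmeansPearson(cl_in, k = k, n_restarts = n_restarts, seed = seed)
    .writeTSV(data.frame(gene_id = names(clus$cluster),
                         cluster = clus$cluster),
              file.path(out_dir, "clusters.tsv"))
    report$expression <- list(n_input = nrow(expression),
                              n_filtered = length(fl$filtered),
                              n_clustered = length(clus$cluster),
                              cluster_sizes = as.list(table(clus$cluster)),
                              objective = clus$objective)
  }

  if ("network" %in% stages) {
    if (is.null(log_mat)) stop("network stage requires expression stage",
                               call. = FALSE)
    net <- tryCatch(buildCoexpressionNetwork(log_mat, min_abs_pcc, alpha),
                    error = function(e) fail("network", e))
    dc <- degreeAndComponents(net)
    .writeTSV(networkEdges(net), file.path(out_dir, "network_edges.tsv"))
    .writeTSV(dc$components, file.path(out_dir, "network_components.tsv"))
    report$network <- list(n_nodes = dc$n_nodes, n_edges = dc$n_edges,
                           n_components = dc$n_components)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
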