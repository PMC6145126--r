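# Synthetic genome generator: gene models (GFF3), CDS/protein FASTA, a
# profile-HMM domain-hit table, homology anchors, and a truth-label set
# covering every planted feature, so each downstream detector can be
# scored against known ground truth.
#
# Layout guarantees:
#  - genes never overlap on a chromosome;
#  - planted tandem arrays are contiguous same-family runs with small
#    internal gaps (every adjacent pair satisfies the <=5-intervening /
#    <100 kb rule);
#  - each tandem array and each collinear-anchor pair carries a dedicated
#    family, and scattered-family members on one chromosome are kept >= 6
#    genes apart, so no unplanted pair can satisfy the tandem rule;
#  - decoy genes carry no hit, an E-value-failing hit, or a
#    coverage-failing hit (long model, short alignment).

#' Configuration for the synthetic kinome genome
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Gene-slot capacity per chromosome.
#' @param n_families Number of scattered (non-tandem) kinase families.
#' @param family_sizes Integer vector (length \code{n_families}) of member
#'   counts.
#' @param n_tandem_arrays Number of planted tandem arrays, each a dedicated
#'   family.
#' @param tandem_array_size Genes per array (2..7; the upper bound keeps
#'   every within-array pair inside the tandem rule).
#' @param n_collinear_blocks Number of planted collinear blocks.
#' @param block_length Anchor pairs per block (>= 5).
#' @param n_decoys Number of non-kinase genes.
#' @param n_noise_anchors Spurious anchors scattered on otherwise unused
#'   chromosome pairs, at most 4 per pair so they can never form a block.
#' @param intergenic_gap c(min, max) bp for ordinary intergenic gaps; the
#'   default straddles the 100 kb tandem threshold so both sides of the
#'   distance rule occur.
#' @param decoy_evalue If set, every decoy carries an E-value-failing hit
#'   at exactly this E-value; if \code{NA} (default) decoys mix the three
#'   failure modes.
#' @param tandem_ks,segmental_ks Target synonymous divergence planted
#'   between tandem array members / collinear anchor partners.  The
#'   defaults (0.25 and 1.2) make tandem duplicates recent and segmental
#'   ones ancient, the pattern typical of plant kinomes.
#' @param kaks_ratio Planted Ka as a fraction of Ks (default 0.3,
#'   purifying).
#' @param seed Integer seed.
#' @return A validated list of class \code{SynthGenomeConfig}.
#' @export
simGenomeConfig <- function(n_chromosomes = 4, genes_per_chromosome = 40,
                            n_families = 6, family_sizes = rep(4L, 6),
                            n_tandem_arrays = 3, tandem_array_size = 2,
                            n_collinear_blocks = 2, block_length = 6,
                            n_decoys = 60, n_noise_anchors = 0,
                            intergenic_gap = c(2e3, 1.5e5),
                            decoy_evalue = NA, tandem_ks = 0.25,
                            segmental_ks = 1.2, kaks_ratio = 0.3,
                            seed = 1) {
  n_chromosomes <- .assertCount(n_chromosomes, "n_chromosomes", 1L)
  genes_per_chromosome <- .assertCount(genes_per_chromosome,
                                       "genes_per_chromosome", 1L)
  n_families <- .assertCount(n_families, "n_families", 0L)
  n_tandem_arrays <- .assertCount(n_tandem_arrays, "n_tandem_arrays", 0L)
  tandem_array_size <- .assertCount(tandem_array_size, "tandem_array_size", 2L)
  if (tandem_array_size > 7)
    stop("'tandem_array_size' above 7 breaks the all-pairs tandem guarantee",
         call. = FALSE)
  n_collinear_blocks <- .assertCount(n_collinear_blocks,
                                     "n_collinear_blocks", 0L)
  if (n_collinear_blocks > 0)
    block_length <- .assertCount(block_length, "block_length", 5L)
  n_decoys <- .assertCount(n_decoys, "n_decoys", 0L)
  family_sizes <- as.integer(family_sizes)
  if (length(family_sizes) != n_families || any(family_sizes < 1))
    stop("'family_sizes' must give a positive size per family", call. = FALSE)
  if (length(intergenic_gap) != 2 || any(intergenic_gap <= 0) ||
      intergenic_gap[1] > intergenic_gap[2])
    stop("'intergenic_gap' must be c(min, max) with 0 < min <= max",
         call. = FALSE)
  total <- sum(family_sizes) + n_tandem_arrays * tandem_array_size +
    2 * n_collinear_blocks * block_length + n_decoys
  if (total > n_chromosomes * genes_per_chromosome)
    stop("config infeasible: ", total, " planted genes exceed capacity ",
         n_chromosomes * genes_per_chromosome, call. = FALSE)
  if (n_collinear_blocks > 0 && n_chromosomes < 2)
    stop("collinear blocks need at least 2 chromosomes", call. = FALSE)
  if (!is.numeric(tandem_ks) || tandem_ks < 0 ||
      !is.numeric(segmental_ks) || segmental_ks < 0 ||
      !is.numeric(kaks_ratio) || kaks_ratio < 0)
    stop("divergence targets must be non-negative", call. = FALSE)
  structure(list(n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 n_families = n_families, family_sizes = family_sizes,
                 n_tandem_arrays = n_tandem_arrays,
                 tandem_array_size = tandem_array_size,
                 n_collinear_blocks = n_collinear_blocks,
                 block_length = block_length, n_decoys = n_decoys,
                 n_noise_anchors = .assertCount(n_noise_anchors,
                                                "n_noise_anchors", 0L),
                 intergenic_gap = as.numeric(intergenic_gap),
                 decoy_evalue = decoy_evalue, tandem_ks = tandem_ks,
                 segmental_ks = segmental_ks, kaks_ratio = kaks_ratio,
                 seed = seed),
            class = "SynthGenomeConfig")
}

# One gene body: exon structure (lengths multiples of 3) and a stop-free
# CDS starting with ATG.
.simGeneBody <- function() {
  n_exons <- sample.int(6, 1)
  exon_len <- 3 * sample(20:90, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(80:500, n_exons - 1, replace = TRUE)
                else integer(0)
  n_codons <- sum(exon_len) / 3
  sense <- .senseCodons()
  cds <- c("ATG", sample(sense, n_codons - 1, replace = TRUE))
  list(exon_len = exon_len, intron_len = intron_len,
       cds = paste(cds, collapse = ""))
}

#' Simulate a kinome genome with known ground truth
#'
#' Generates the full input set of the pipeline: gene/transcript/exon/CDS
#' models, CDS and protein sequences, a domain-hit table whose acceptance
#' status under the identification filter is recorded per gene, planted
#' tandem arrays, planted collinear anchor blocks, decoy genes, and truth
#' labels for all of them.  Deterministic for a given config.
#'
#' @param config A \code{\link{simGenomeConfig}}.
#' @return List: \code{gff} (a \code{GRanges} ready for
#'   \code{\link[rtracklayer]{export}}), \code{models} (the
#'   \code{\link{gffGeneModels}} tables), \code{cds} / \code{proteins}
#'   (named \code{DNAStringSet} / \code{AAStringSet}), \code{hits}
#'   (domain-hit data.frame), \code{anchors} (anchor-pair data.frame), and
#'   \code{truth} (planted kinases with family/group and filter status,
#'   tandem arrays, blocks, decoys, per-gene intron counts).
#' @export
simKinomeGenome <- function(config) {
  stopifnot(inherits(config, "SynthGenomeConfig"))
  withSeed(config$seed, {
    nchr <- config$n_chromosomes
    cap <- rep(config$genes_per_chromosome, nchr)
    chrom_names <- sprintf("chr%02d", seq_len(nchr))

    units <- list()   # each: list(genes=data.frame(label, family, role), tight)
    add_unit <- function(chrom, labels, families, roles, tight) {
      units[[length(units) + 1L]] <<- list(
        chrom = chrom, labels = labels, families = families, roles = roles,
        tight = tight)
      cap[chrom] <<- cap[chrom] - length(labels)
    }
    pick_chrom <- function(need, exclude = integer(0)) {
      ok <- setdiff(which(cap >= need), exclude)
      if (length(ok) == 0L)
        stop("config infeasible: no chromosome capacity left", call. = FALSE)
      ok[which.max(cap[ok])]
    }

    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("Syn%05d", gid)
    }

    blocks_truth <- list()
    for (b in seq_len(config$n_collinear_blocks)) {
      L <- config$block_length
      ca <- pick_chrom(L)
      cb <- pick_chrom(L, exclude = ca)
      fam <- sprintf("BLK%02d_a%02d", b, seq_len(L))
      ga <- vapply(seq_len(L), function(i) next_id(), character(1))
      gb <- vapply(seq_len(L), function(i) next_id(), character(1))
      add_unit(ca, ga, fam, rep("block", L), tight = FALSE)
      add_unit(cb, gb, fam, rep("block", L), tight = FALSE)
      blocks_truth[[b]] <- data.frame(block = b, gene_a = ga, gene_b = gb,
                                      chrom_a = chrom_names[ca],
                                      chrom_b = chrom_names[cb],
                                      family = fam, stringsAsFactors = FALSE)
    }

    arrays_truth <- list()
    for (a in seq_len(config$n_tandem_arrays)) {
      m <- config$tandem_array_size
      ch <- pick_chrom(m)
      fam <- sprintf("TDF%02d", a)
      g <- vapply(seq_len(m), function(i) next_id(), character(1))
      add_unit(ch, g, rep(fam, m), rep("tandem", m), tight = TRUE)
      arrays_truth[[a]] <- data.frame(array = a, gene_id = g, family = fam,
                                      chrom = chrom_names[ch],
                                      stringsAsFactors = FALSE)
    }

    scattered <- list()
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("FAM%s_%02d",
                     LETTERS[(f - 1) %% length(LETTERS) + 1], f)
      for (m in seq_len(config$family_sizes[f])) {
        ch <- pick_chrom(1)
        g <- next_id()
        add_unit(ch, g, fam, "single", tight = FALSE)
        scattered[[length(scattered) + 1L]] <-
          data.frame(gene_id = g, family = fam, stringsAsFactors = FALSE)
      }
    }

    decoy_ids <- character(config$n_decoys)
    for (d in seq_len(config$n_decoys)) {
      ch <- pick_chrom(1)
      g <- next_id()
      decoy_ids[d] <- g
      add_unit(ch, g, NA_character_, "decoy", tight = FALSE)
    }

    # ---- gene bodies: duplicate genes are codon-diverged copies of a
    # shared ancestor so Ka/Ks carries the planted signal ----------------
    bodies <- list()
    diverge_body <- function(body, ks, ka) {
      div <- .divergeCodons(.splitCodons(body$cds), .jcInverse(ks),
                            .jcInverse(ka))
      list(exon_len = body$exon_len, intron_len = body$intron_len,
           cds = paste(div$codons, collapse = ""))
    }
    for (bt in blocks_truth) {
      for (i in seq_len(nrow(bt))) {
        anc <- .simGeneBody()
        bodies[[bt$gene_a[i]]] <- anc
        bodies[[bt$gene_b[i]]] <- diverge_body(anc, config$segmental_ks,
                                               config$kaks_ratio *
                                                 config$segmental_ks)
      }
    }
    for (at in arrays_truth) {
      anc <- .simGeneBody()
      bodies[[at$gene_id[1]]] <- anc
      for (k in seq_len(nrow(at))[-1])
        bodies[[at$gene_id[k]]] <- diverge_body(anc, config$tandem_ks,
                                                config$kaks_ratio *
                                                  config$tandem_ks)
    }
    for (u in units) {
      for (lab in u$labels)
        if (is.null(bodies[[lab]])) bodies[[lab]] <- .simGeneBody()
    }

    # ---- order units within each chromosome, keeping same-family singles
    # >= 6 genes apart --------------------------------------------------
    ordered_units <- vector("list", nchr)
    for (ch in seq_len(nchr)) {
      uidx <- which(vapply(units, function(u) u$chrom == ch, logical(1)))
      if (length(uidx) == 0L) next
      uidx <- sample(uidx)                    # random base order
      seq_out <- integer(0)
      recent <- character(0)                  # families of last 6 genes
      remaining <- uidx
      single_fam <- vapply(remaining, function(i) {
        u <- units[[i]]
        f <- u$families[u$roles == "single"]
        if (length(f)) f[1] else NA_character_
      }, character(1))
      while (length(remaining) > 0L) {
        eligible <- is.na(single_fam) | !(single_fam %in% recent)
        if (!any(eligible))
          stop("config infeasible: cannot keep same-family genes >= 6 ",
               "genes apart on ", chrom_names[ch], call. = FALSE)
        # most-constrained first: place the single from the family with
        # the most members still waiting; fillers only when every waiting
        # single is inside the cooldown window
        cand <- which(eligible & !is.na(single_fam))
        pos <- if (length(cand) > 0L) {
          load <- table(single_fam[!is.na(single_fam)])
          cand[which.max(load[single_fam[cand]])]
        } else {
          which(eligible)[1]
        }
        u <- units[[remaining[pos]]]
        seq_out <- c(seq_out, remaining[pos])
        recent <- utils::tail(c(recent, rep(single_fam[pos],
                                            length(u$labels))), 6)
        remaining <- remaining[-pos]
        single_fam <- single_fam[-pos]
      }
      ordered_units[[ch]] <- seq_out
    }

    # ---- assign coordinates, bodies, strands --------------------------
    gap_rng <- config$intergenic_gap
    gene_rows <- list()
    for (ch in seq_len(nchr)) {
      pos <- 1
      rank <- 0L
      for (ui in ordered_units[[ch]]) {
        u <- units[[ui]]
        for (i in seq_along(u$labels)) {
          gap <- if (i > 1 && u$tight) runif(1, 2e3, 1.5e4)
                 else runif(1, gap_rng[1], gap_rng[2])
          pos <- pos + round(gap)
          body <- bodies[[u$labels[i]]]
          glen <- sum(body$exon_len) + sum(body$intron_len)
          rank <- rank + 1L
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = u$labels[i], chrom = chrom_names[ch],
            start = pos, end = pos + glen - 1,
            strand = sample(c("+", "-"), 1),
            family = u$families[i], role = u$roles[i], rank = rank,
            stringsAsFactors = FALSE)
          bodies[[u$labels[i]]] <- body
          pos <- pos + glen
        }
      }
    }
    genes <- do.call(rbind, gene_rows)

    # ---- GFF3 records -------------------------------------------------
    feat <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      body <- bodies[[g$gene_id]]
      tx_id <- paste0(g$gene_id, ".1")
      exon_starts <- g$start + cumsum(c(0, head(body$exon_len, -1) +
                                           body$intron_len))
      exon_ends <- exon_starts + body$exon_len - 1
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = g$chrom,
        start = c(g$start, g$start, exon_starts, exon_starts),
        end = c(g$end, g$end, exon_ends, exon_ends),
        strand = g$strand,
        type = c("gene", "mRNA", rep("exon", length(exon_starts)),
                 rep("CDS", length(exon_starts))),
        ID = c(g$gene_id, tx_id,
               paste0(tx_id, ".exon", seq_along(exon_starts)),
               paste0(tx_id, ".cds", seq_along(exon_starts))),
        Parent = c(NA, g$gene_id, rep(tx_id, 2 * length(exon_starts))),
        stringsAsFactors = FALSE)
    }
    feat <- do.call(rbind, feat)
    gff <- GenomicRanges::GRanges(
      seqnames = feat$chrom,
      ranges = IRanges::IRanges(feat$start, feat$end),
      strand = feat$strand)
    gff$type <- feat$type
    gff$ID <- feat$ID
    gff$Parent <- feat$Parent
    # exon lengths are codon multiples, so every CDS segment starts in frame
    gff$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)

    # ---- sequences ----------------------------------------------------
    cds_seq <- vapply(genes$gene_id, function(g) bodies[[g]]$cds, character(1))
    names(cds_seq) <- paste0(genes$gene_id, ".1")
    cds <- Biostrings::DNAStringSet(cds_seq)
    proteins <- Biostrings::translate(cds)

    # ---- domain hits --------------------------------------------------
    kin <- genes[genes$role != "decoy", , drop = FALSE]
    prot_len <- nchar(cds_seq) / 3
    hit_rows <- list()
    add_hit <- function(protein, model, mlen, sev, dev, bit, hf, ht, af, at)
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        protein_id = protein, model_name = model, model_length = mlen,
        seq_evalue = sev, dom_evalue = dev, bit_score = bit,
        hmm_from = hf, hmm_to = ht, ali_from = af, ali_to = at,
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(kin))) {
      p <- paste0(kin$gene_id[i], ".1")
      plen <- prot_len[[p]]
      dev <- 10^-runif(1, 8, 40)
      span <- sample(130:260, 1)               # coverage >= 0.5 of 260
      af <- sample.int(max(plen - 50, 1), 1)
      add_hit(p, sample(catalyticModels(), 1), 260, dev / 10, dev,
              round(runif(1, 120, 500), 1), 1, span,
              af, min(af + span - 1, plen))
      # family-model hit: own family wins, a rival family scores lower
      own_bit <- round(runif(1, 250, 400), 1)
      add_hit(p, kin$family[i], 250, 1e-30, 1e-28, own_bit, 1, 250, 1,
              min(250, plen))
      if (runif(1) < 0.5)
        add_hit(p, "FAM_rival", 250, 1e-10, 1e-8,
                round(own_bit - runif(1, 30, 120), 1), 1, 180, 1,
                min(180, plen))
    }
    decoy_mode <- character(config$n_decoys)
    if (config$n_decoys > 0) {
      modes <- if (!is.na(config$decoy_evalue)) rep("evalue", config$n_decoys)
               else sample(c("none", "evalue", "coverage"),
                           config$n_decoys, replace = TRUE)
      for (d in seq_len(config$n_decoys)) {
        p <- paste0(decoy_ids[d], ".1")
        plen <- prot_len[[p]]
        decoy_mode[d] <- modes[d]
        if (modes[d] == "evalue") {
          ev <- if (!is.na(config$decoy_evalue)) config$decoy_evalue else 1e-3
          add_hit(p, "Pkinase", 260, ev, ev, round(runif(1, 10, 30), 1),
                  1, 200, 1, min(200, plen))
        } else if (modes[d] == "coverage") {
          # strong E-value but alignment covering < 50% of the model
          add_hit(p, "Pkinase", 260, 1e-12, 1e-10,
                  round(runif(1, 40, 80), 1), 1, sample(40:129, 1),
                  1, min(100, plen))
        }
      }
    }
    hits <- do.call(rbind, hit_rows)
    rownames(hits) <- NULL

    # ---- anchors ------------------------------------------------------
    rank_of <- setNames(genes$rank, genes$gene_id)
    anchor_rows <- lapply(blocks_truth, function(bt) {
      data.frame(gene_a = bt$gene_a, gene_b = bt$gene_b,
                 chrom_a = bt$chrom_a, chrom_b = bt$chrom_b,
                 rank_a = as.integer(rank_of[bt$gene_a]),
                 rank_b = as.integer(rank_of[bt$gene_b]),
                 stringsAsFactors = FALSE)
    })
    anchors <- if (length(anchor_rows)) do.call(rbind, anchor_rows) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 chrom_a = character(0), chrom_b = character(0),
                 rank_a = integer(0), rank_b = integer(0),
                 stringsAsFactors = FALSE)
    if (config$n_noise_anchors > 0) {
      pool <- genes$gene_id[genes$role == "decoy"]
      n_noise <- min(config$n_noise_anchors, length(pool) %/% 2, 4L)
      if (n_noise > 0) {
        a <- pool[seq_len(n_noise)]
        b <- pool[seq_len(n_noise) + n_noise]
        anchors <- rbind(anchors, data.frame(
          gene_a = a, gene_b = b,
          chrom_a = genes$chrom[match(a, genes$gene_id)],
          chrom_b = genes$chrom[match(b, genes$gene_id)],
          rank_a = as.integer(rank_of[a]), rank_b = as.integer(rank_of[b]),
          stringsAsFactors = FALSE))
      }
    }

    truth <- list(
      kinases = data.frame(
        gene_id = kin$gene_id, protein_id = paste0(kin$gene_id, ".1"),
        family = kin$family, group = familyGroup(kin$family),
        role = kin$role, accepted = TRUE, stringsAsFactors = FALSE),
      decoys = data.frame(gene_id = decoy_ids, mode = decoy_mode,
                          accepted = FALSE, stringsAsFactors = FALSE),
      tandem_arrays = if (length(arrays_truth)) do.call(rbind, arrays_truth)
        else data.frame(array = integer(0), gene_id = character(0),
                        family = character(0), chrom = character(0)),
      blocks = if (length(blocks_truth)) do.call(rbind, blocks_truth)
        else data.frame(block = integer(0), gene_a = character(0),
                        gene_b = character(0), chrom_a = character(0),
                        chrom_b = character(0), family = character(0)),
      intron_counts = setNames(
        vapply(genes$gene_id, function(g)
          length(bodies[[g]]$exon_len) - 1L, integer(1)),
        genes$gene_id),
      genes = genes)

    models <- list(
      genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
      transcripts = data.frame(
        tx_id = paste0(genes$gene_id, ".1"), gene_id = genes$gene_id,
        n_exons = vapply(genes$gene_id, function(g)
          length(bodies[[g]]$exon_len), integer(1)),
        cds_length = vapply(genes$gene_id, function(g)
          sum(bodies[[g]]$exon_len), numeric(1)),
        stringsAsFactors = FALSE),
      exons = {
        ei <- feat[feat$type == "exon", , drop = FALSE]
        data.frame(tx_id = ei$Parent, start = ei$start, end = ei$end,
                   stringsAsFactors = FALSE)
      })

    list(gff = gff, models = models, cds = cds, proteins = proteins,
         hits = hits, anchors = anchors, truth = truth, config = config)
  })
}

#' Write a simulated genome to disk
#'
#' Writes the GFF3, CDS and protein FASTA, domain-hit table, anchor table
#' and truth labels (JSON) of a \code{\link{simKinomeGenome}} result.
#' Re-running with the same config and seed reproduces the files
#' byte-identically.
#'
#' @param sim Result of \code{\link{simKinomeGenome}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeKinomeSim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gff = file.path(dir, "genome.gff3"),
             cds = file.path(dir, "cds.fasta"),
             proteins = file.path(dir, "proteins.fasta"),
             hits = file.path(dir, "domain_hits.tsv"),
             anchors = file.path(dir, "anchors.tsv"),
             truth = file.path(dir, "truth.json"))
  rtracklayer::export(sim$gff, paths[["gff"]], format = "gff3")
  Biostrings::writeXStringSet(sim$cds, paths[["cds"]])
  Biostrings::writeXStringSet(sim$proteins, paths[["proteins"]])
  hdr <- paste0("# ", paste(colnames(sim$hits), collapse = "\t"))
  writeLines(hdr, paths[["hits"]])
  suppressWarnings(write.table(sim$hits, paths[["hits"]], sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               col.names = FALSE, append = TRUE))
  write.table(sim$anchors, paths[["anchors"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$intron_counts <- as.list(truth$intron_counts)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
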