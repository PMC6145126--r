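# Simulated CDS pairs with controlled synonymous / nonsynonymous
# divergence.  Changes are planted per codon (at most one synonymous and
# one nonsynonymous single-base change, at distinct positions), with
# per-codon inclusion probabilities chosen so that the expected uncorrected
# proportions pS and pN equal the Jukes-Cantor inverses of the target Ks
# and Ka.  No internal stop codons are ever created.

#' Configuration for a simulated codon pair
#'
#' @param n_codons Number of codons (>= 30).
#' @param target_ks,target_ka Target synonymous / nonsynonymous distances
#'   (substitutions per site, after JC correction; must stay below the
#'   saturation regime p < 3/4).
#' @param seed Integer seed.
#' @return A validated list of class \code{CodonPairConfig}.
#' @export
simCodonPairConfig <- function(n_codons = 300, target_ks = 0.3,
                               target_ka = 0.1, seed = 1) {
  n_codons <- .assertCount(n_codons, "n_codons", min = 30L)
  if (!is.numeric(target_ks) || target_ks < 0 ||
      !is.numeric(target_ka) || target_ka < 0)
    stop("targets must be non-negative", call. = FALSE)
  structure(list(n_codons = n_codons, target_ks = target_ks,
                 target_ka = target_ka, seed = seed),
            class = "CodonPairConfig")
}

# JC distance -> expected raw proportion of differences per site.
.jcInverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# synonymous / nonsynonymous non-stop single-base substitutions of a codon
.codonChanges <- function(codon) {
  code <- .geneticCode()
  aa <- code[[codon]]
  nb <- .codonNeighbors(codon)
  nb <- nb[code[nb] != "*"]
  pos <- vapply(nb, function(x) {
    which(strsplit(x, "")[[1]] != strsplit(codon, "")[[1]])[1]
  }, integer(1))
  list(syn = nb[code[nb] == aa], syn_pos = pos[code[nb] == aa],
       nonsyn = nb[code[nb] != aa], nonsyn_pos = pos[code[nb] != aa])
}

.changeTable <- function() {
  if (is.null(.kk$changes))
    .kk$changes <- lapply(setNames(nm = .senseCodons()), .codonChanges)
  .kk$changes
}

# Plant synonymous/nonsynonymous changes on a codon vector so the expected
# NG86 proportions equal pS_t / pN_t.  Uses the caller's RNG stream.
.divergeCodons <- function(ca, pS_t, pN_t) {
  st <- .siteTable()
  n <- length(ca)
  S <- sum(st[ca])
  N <- 3 * n - S
  ch <- .changeTable()
  syn_ok <- vapply(ca, function(c) length(ch[[c]]$syn) > 0, logical(1))
  p_syn <- if (pS_t > 0) (pS_t * S) / sum(syn_ok) else 0
  p_non <- if (pN_t > 0) (pN_t * N) / n else 0
  if (p_syn > 1 || p_non > 1)
    stop("target divergence unreachable for this codon composition",
         call. = FALSE)
  cb <- ca
  planted_syn <- 0L
  planted_non <- 0L
  for (i in seq_len(n)) {
    used_pos <- integer(0)
    if (syn_ok[i] && runif(1) < p_syn) {
      opts <- ch[[ca[i]]]
      pick <- sample.int(length(opts$syn), 1)
      cb[i] <- opts$syn[pick]
      used_pos <- opts$syn_pos[pick]
      planted_syn <- planted_syn + 1L
    }
    if (p_non > 0 && runif(1) < p_non) {
      # nonsynonymous change on top of the (possibly) mutated codon, at a
      # position not already used, never creating a stop
      opts <- ch[[cb[i]]]
      okp <- which(!(opts$nonsyn_pos %in% used_pos))
      if (length(okp) > 0) {
        pick <- okp[sample.int(length(okp), 1)]
        cb[i] <- opts$nonsyn[pick]
        planted_non <- planted_non + 1L
      }
    }
  }
  list(codons = cb, planted_synonymous = planted_syn,
       planted_nonsynonymous = planted_non, S = S, N = N)
}

#' Generate a codon-diverged CDS pair with known ground truth
#'
#' Draws a random stop-free CDS and derives a partner by planting
#' synonymous and nonsynonymous codon changes so that the expected NG86
#' proportions match the targets' uncorrected equivalents.  Deterministic
#' for a given config.
#'
#' @param config A \code{\link{simCodonPairConfig}}.
#' @return List: \code{cds_a}, \code{cds_b} (character strings, equal
#'   length, gapless, stop-free), and \code{truth} with the planted
#'   synonymous/nonsynonymous change counts and target proportions.
#' @examples
#' p <- simCodonPair(simCodonPairConfig(60, target_ks = 0, target_ka = 0))
#' identical(p$cds_a, p$cds_b)
#' @export
simCodonPair <- function(config) {
  stopifnot(inherits(config, "CodonPairConfig"))
  withSeed(config$seed, {
    sense <- .senseCodons()
    ca <- sample(sense, config$n_codons, replace = TRUE)
    pS_t <- .jcInverse(config$target_ks)
    pN_t <- .jcInverse(config$target_ka)
    div <- .divergeCodons(ca, pS_t, pN_t)
    list(cds_a = paste(ca, collapse = ""),
         cds_b = paste(div$codons, collapse = ""),
         truth = list(planted_synonymous = div$planted_synonymous,
                      planted_nonsynonymous = div$planted_nonsynonymous,
                      pS_target = pS_t, pN_target = pN_t,
                      S = div$S, N = div$N))
  })
}
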