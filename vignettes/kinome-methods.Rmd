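---
title: "Methods: kinome annotation, duplication, selection and coexpression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinome annotation, duplication, selection and coexpression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomeEvo)
```

# Scope and model of the data

Plant kinomes are large (hundreds to thousands of genes), dominated by
the receptor-like kinase (RLK/Pelle) group, and shaped by tandem and
segmental duplication. This package implements the analytical core of a
kinome study as pure, seeded functions over four kinds of input: gene
models (GFF3), coding and protein sequences (FASTA), per-domain
profile-HMM hit tables, and FPKM expression matrices. Each stage is
paired with a synthetic-data generator that plants the structure the
stage is supposed to find, so correctness is always measured against
known truth.

# Kinase identification and classification

A protein enters the catalog iff at least one catalytic-model hit
(Pkinase or Pkinase_Tyr by default) passes two filters:

* per-domain independent E-value strictly below `evalue_max`
  (default 1e-5). The cutoff could equally be applied to the
  full-sequence E-value; published descriptions rarely say which. We
  default to the per-domain value because the coverage rule below is a
  per-domain statement, and expose `evalue_on = "sequence"` as a flag.
* model coverage `(hmm_to − hmm_from + 1) / model_length` of at least
  `min_model_coverage` (default 0.5), inclusive at the boundary. Both
  boundary behaviors (E-value strict, coverage inclusive) are fixed
  contracts, tested at exactly 1e-5 and exactly 50%.

Family assignment takes the highest bit score among accepted
family-model hits; the group is the family prefix before the first
underscore, with `RLK-Pelle` reported as `RLK`. Exact ties are broken
lexicographically and *flagged*, and the margin between best and
second-best scores is reported: in a real study ambiguous assignments
would be re-examined with a phylogeny, which is out of scope here, so
ambiguity must at least be visible. Proteins with no accepted family hit
are `unclassified` (family and group).

Kinase-domain multiplicity counts accepted catalytic hits after merging
hits whose protein-coordinate overlap exceeds 50% of the shorter
interval (transitively). Profile searches frequently split one domain
into two partial alignments; without the merge, such splits would
inflate multi-domain counts.

Intron counts are exon count minus one on the *representative*
transcript, chosen as the longest total CDS (ties by transcript id).
Published intron counts rarely state the isoform convention; longest-CDS
is the common genome-database default.

# Tandem and segmental duplication

The tandem rule: two genes of the same family, on the same chromosome,
separated by at most 5 intervening genes and by less than 100 kb. Three
reading choices had to be fixed:

* *intervening genes* counts all annotated genes between the pair, not
  only kinases — "separated by N genes" refers to genomic neighbors;
* *distance* is measured between nearest gene boundaries (upstream end
  to downstream start), since no measurement point is standard;
* the gene-count bound is inclusive (≤ 5) and the distance bound strict
  (< 100 kb), matching the usual wording "five or fewer" / "less than".

Arrays are connected components of the pairwise relation; both
pair-level and array-level counts are reported because "N tandem events"
is ambiguous between the two in the literature.

Segmental duplicates come from collinear blocks. Full synteny tools
combine alignment scoring, gap penalties and E-value models; here
collinearity is deliberately reduced to its core: a block is a maximal
chain of anchor pairs strictly monotone in gene rank on both chromosomes
(increasing/increasing or increasing/decreasing for inverted blocks),
with at most `max_gap = 25` skipped ranks between consecutive anchors
and at least `min_block = 5` anchors — the documented defaults of the
standard tool. Chains are extracted greedily by length (ties by smaller
rank span), each anchor belonging to at most one block. Anchor pairs
(homology calls) are an input; generating them by sequence similarity is
out of scope, and the synthetic genome ships truth-label anchors.

# Ka/Ks by Nei–Gojobori counting

The NG86 estimator is implemented from first principles:

* **Sites.** For a codon, each position contributes
  (synonymous single-base changes) / (single-base changes not creating a
  stop); s summed over positions, n = 3 − s. Stop-avoiding denominators
  are the standard convention.
* **Differences.** Codon pairs differing at k positions are averaged
  over all k! orderings of single-base steps; pathways through stop
  codons are excluded (if all pathways are blocked — possible for a few
  sense-codon pairs — the average falls back to all pathways).
* **Correction.** With pS = Sd/S and pN = Nd/N (sites averaged over the
  two sequences), d = −(3/4)·ln(1 − 4p/3). The correction is undefined
  at p ≥ 3/4; such results carry an `NA` with the rest of the record
  intact, distinct from the Ks = 0 case where the *ratio* is undefined
  but Ks is a valid zero.
* **Selection.** Ka/Ks below 1 is purifying, above 1 positive; equality
  within 1e-9 is reported as neutral.

Site and difference counts per codon (pair) are precomputed into lookup
tables at first use, so whole-CDS estimates are table sums; the tables
themselves are verified against exhaustive enumeration in the tests.
`kaKs(a, b)` is exactly symmetric. Codon alignment accepts equal-length
gapless CDS directly or back-translates a supplied protein alignment
(gap columns dropped, translations verified); a shared terminal stop is
tolerated and dropped, internal stops are errors.

Ks histograms use half-open bins [k·w, (k+1)·w) with w = 0.1 by
default — the binning used to compare duplication-cohort ages —
excluding and tallying saturated values.

# Alternative splicing

Events are defined pairwise on intron chains (identical chains,
including UTR-only differences, are "no event"):

* **Intron retention**: an intron of one isoform fully inside an exon of
  the other.
* **Alt acceptor / donor**: two overlapping introns sharing the donor
  (5′, strand-resolved) boundary but not the acceptor, or vice versa.
* **Exon skipping**: an exon strictly inside a single intron of the
  other isoform whose flanking introns share that intron's outer
  boundaries.
* Overlapping introns differing at both boundaries that fit none of the
  above contribute an unclassifiable difference.

The gene-level category is the union over all isoform pairs: one
elementary type labels the gene with it; two or more types, or any
unclassifiable difference, gives "complex". These operational
definitions replace database lookups used in survey papers, which do not
publish their internal rules; the synthetic isoform generator
(`simIsoforms`) constructs fixtures exhibiting exactly one event of each
type on either strand, so the classifier's agreement with the intended
taxonomy is tested directly.

# Expression filtering and clustering

Genes whose FPKM stays below 10 in *every* sample are lowly expressed
and removed (strictly below: one sample at exactly 10 retains the gene).
Profiles are transformed to log2(FPKM + 1). Clustering uses k-means with
Pearson correlation distance d = 1 − r, mean centroids, and the best of
`n_restarts` seeded initializations. Numerical choices:

* correlation against a zero-variance centroid is assigned the maximal
  distance 2 so iterations always terminate;
* empty clusters are re-seeded from the point farthest from its
  centroid;
* zero-variance gene rows (distance undefined) are removed up front and
  reported.

Whether published clusterings ran on raw or log FPKM is typically
unstated; clustering here defaults to log profiles (`cluster_on_log`
flag in the pipeline). k defaults to 10, the conventional choice for
kinome expression atlases.

# Coexpression networks

All row pairs with |r| strictly above `min_abs_pcc` (default 0.8; 0.9
variant for duplicate-gene networks) at two-sided p strictly below 0.01
become edges. The significance test is the exact-under-normality t
reference, t = r·sqrt((n−2)/(1−r²)) on n−2 degrees of freedom — papers
citing a statistics GUI at "the 0.01 significance level" almost
certainly used this test. The tests cross-check it against a
1e6-shuffle permutation null at (r, n) grid points; the comparison
tolerance is four Monte-Carlo standard errors plus 15% of the t-based
p-value, the latter covering the O(1/n) gap between the conditional
permutation distribution and the unconditional t reference at n = 14–24.
No multiple-testing correction is applied by default (an optional
Benjamini–Hochberg flag exists), matching common practice for these
descriptive networks. Gene-level and family-averaged matrices go through
the same code path. Degrees and connected components come from igraph;
nodes without edges are not reported.

For diurnal data the two leaf-section series (12 + 12 time points) are
concatenated into one 24-point profile per gene, mirroring the joint
photosynthetic/non-photosynthetic analysis such data are collected for.

# The synthetic-data generators

`simKinomeGenome` emulates the *structure* a kinome study consumes:
chromosomes with non-overlapping genes, gene→mRNA→exon/CDS hierarchies
(1-based, closed intervals, random strands), planted kinase families
with passing domain hits, decoys failing specifically the E-value or
the coverage rule (long model, short alignment), tandem arrays as
contiguous same-family runs with small internal gaps, collinear blocks
as rank-ordered anchor series on two chromosomes, and duplicate genes
derived from a shared ancestral CDS with planted synonymous divergence
(defaults: tandem Ks 0.25, segmental Ks 1.2, Ka/Ks 0.3 — recent tandem,
ancient segmental, purifying throughout, the pattern typical of plant
kinomes). Intergenic gaps are drawn from 2–150 kb so the 100 kb tandem
threshold is exercised on both sides, and the layout keeps same-family
genes that are *not* in one array at least 6 genes apart, so planted
arrays are exactly the gene sets satisfying the tandem rule.

`simCodonPair` plants at most one synonymous and one nonsynonymous
single-base change per codon (distinct positions, never creating
stops), with per-codon probabilities chosen so the *expected* NG86
proportions equal the Jukes–Cantor inverses of the targets. Ks-only
recovery is unbiased; combining high Ks with nonzero Ka introduces a
small (≈5% at Ks = 1) downward interaction bias from pathway averaging
over doubly mutated codons, well inside the 15% recovery tolerance the
tests assert. Unreachable targets (per-codon probability above 1) raise
an error rather than silently truncating.

`simExpressionData` plants cluster structure: lowly expressed genes draw
uniform values in [0, 10), expressed genes are Gaussian noise around
their cluster's mean profile (truncated at zero, re-drawn in the rare
case every value lands below 10, so the planted expressed/low partition
is exact). Default profiles are smooth bumps peaking at distinct
samples, scaled 15–120 FPKM. On the 14-sample developmental panel ten
bump profiles are crowded and recovery is imperfect by design; the
recovery benchmarks therefore use the 24-sample diurnal panel, where the
ten planted clusters are well separated under correlation distance.

What the generators do **not** emulate: sequence-level homology (the
collinearity detector consumes anchor tables, not alignments), realistic
base composition or intron sequence, read-level noise, isoform
expression, or correlated noise across samples. Passing tests therefore
demonstrate algorithmic correctness against the stated rules and
distributions, not robustness to the full messiness of real RNA-seq and
annotation pipelines.

# Determinism and problem sizes

Every stochastic entry point takes an explicit seed and runs on a
private RNG stream, so identical configs reproduce outputs byte for
byte (asserted for files and pipeline reports). The test suite sizes
its simulations for completeness per unit time: 1000-codon-pair oracle
sweeps, 100 replicates × 4 Ks targets at 900 codons, 50 random layouts
for the tandem oracle, brute-force chain oracles at ≤ 30 anchors, a
500-gene clustering benchmark, and a 1e6-shuffle permutation
calibration — enough for the stated tolerances while keeping the whole
suite in the minutes range.

# Known limitations

* NG86 with JC correction ignores transition/transversion bias and
  codon-usage structure; maximum-likelihood (GY94-type) estimators are
  out of scope, so absolute Ka/Ks on real data will differ slightly
  from tools defaulting to other models.
* The collinearity detector is a simplification; on real genomes it
  approximates, not reproduces, full synteny tools.
* AS classification covers the four elementary types plus "complex";
  mutually exclusive exons and alternative TSS/TES are not subtyped.
* The tandem caller needs *all* annotated genes, not only kinases, to
  count intervening genes correctly — passing a kinase-only table
  silently weakens the rule.
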