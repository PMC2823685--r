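---
title: "Reconstructing bacterial Zur regulons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing bacterial Zur regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zurscan)
library(dplyr)
```

## The biological problem

Zur is the zinc-sensing repressor of the Fur family that controls zinc
homeostasis in actinobacteria. When intracellular zinc is replete, Zur
binds a conserved 21-bp palindromic operator — a 10-1-10 inverted repeat
with a non-palindromic centre base — that overlaps the −35 element or the
whole −10/−35 core of its target promoters, sterically blocking RNA
polymerase. Its regulon centres on zinc ABC-type uptake transporters
(`znuACB`), a COG0523 P-loop GTPase thought to act as a zinc
metallochaperone, and associated genes. Because individual genomes offer
only a handful of operator instances, regulon reconstruction leans on
comparative genomics: a motif learned from orthologous upstream regions is
used to scan many genomes, and candidate sites are kept only when they
recur in front of orthologous genes — the *consistency check*.

This vignette records the package's modelling choices, the parameters that
matter, and what the synthetic benchmark does and does not establish.

## The motif model

`build_motif()` accumulates per-column base counts `N(b,k)` from training
sites and converts them to centred log-count weights

$$w(b,k) = \ln\big(N(b,k)+c\big) - \tfrac{1}{4}\sum_{b'}\ln\big(N(b',k)+c\big),$$

with pseudocount $c$ (default 0.5, configurable). Two properties motivate
this form:

* **column-sum zero** — every column's four weights sum to zero exactly, so
  scores of unrelated sequences are centred rather than drifting with the
  motif's composition;
* **counts-only dependence** — no background model enters, which keeps the
  weights reproducible from the serialized count matrix alone.

The **Z-score** of a candidate site is the sum of its positional weights
(`score_sites()`). Natural logarithms are used throughout; the choice is
arbitrary but fixed, so scores are comparable across runs and serialized
models.

**Palindromic symmetrization.** For a dyad-symmetric regulator, each
training site also contributes its reverse complement to the counts, giving
`w(b,k) = w(comp(b), W−1−k)` exactly. Scoring averages the forward and
reverse readings of a window — the two readings contain the same weight
terms, so `score(s) == score(revcomp(s))` holds to the last bit, and a scan
reports each palindromic locus once, on the forward strand. This is what
lets a single operator in a 29-bp intergenic gap serve two divergently
transcribed units.

**Threshold.** `set_threshold_from_training()` sets the scan threshold to
the *minimum training-site score*. No numeric threshold is hard-coded: the
published genome-scale value for this regulator (Z = 4.8) belongs to a
16-genome training compendium that is not an input here, and any threshold
carried across training sets would be meaningless. By construction no
training site is rejected by its own model.

**Information content** per column is $IC_k = 2 + \sum_b f(b,k)\log_2
f(b,k)$ with pseudocounted frequencies; the consensus is the per-column
count argmax with alphabetical tie-breaking (ties are flagged, not hidden).

## Motif discovery

`discover_motif()` implements a one-occurrence-per-sequence site sampler:
one window per region, iteratively re-chosen against the model built from
all *other* regions' windows (both strands), under the palindromic
constraint. Numerical choices:

* **Objective and monotonicity.** The objective is the total information
  content of the model built from all chosen windows. A full update pass is
  accepted only if it strictly increases the objective; otherwise the
  previous state is restored and the restart terminates. This makes the
  trajectory non-decreasing by construction — a property the test suite
  asserts — at the cost of occasionally stopping one pass early.
* **Restarts and seeding.** Multiple random restarts (default 10); the
  restart with the highest objective wins. All randomness flows through a
  single seed, so identical inputs and seed give identical output.
* **Tie-breaking.** Equal-scoring windows resolve to the leftmost position,
  forward strand first.
* **Width parity.** Palindromic discovery requires an odd width: the
  operator class modelled here is an inverted repeat around an unpaired
  centre base.
* **Siteless regions.** After convergence the returned model carries its
  training-minimum threshold. Dropping windows below *that* threshold is
  vacuous by construction; the drop rule has force only when an explicit,
  stricter `threshold` is supplied, subject to `min_regions_with_site`.
  One site per region is the default and only mode; whether the historical
  tool allowed multiple sites per sequence is not documented, and a single
  occurrence matches the observed one-operator-per-promoter architecture.

## Genome scanning and regulon assembly

Coordinates are **0-based half-open on the forward strand** everywhere
inside the package; GFF3 and the TSV gene-table dialect (both 1-based
inclusive) convert at the I/O boundary. This removes the off-by-one
ambiguity that plagues mixed-convention pipelines.

* **Upstream windows** default to −300..+50 nt around the translation
  start, oriented in gene sense. The window is a package choice: published
  site placements for this regulator (including a distal site 167 nt
  upstream of a transcription start) all fall inside it. Windows truncate
  at linear contig edges and wrap on circular ones; a window fully off the
  contig is an empty, flagged region, not an error.
* **Site assignment** anchors on the site centre (`position + 10` for
  width 21): a site is assigned to every gene whose window covers its
  centre. Divergent pairs can therefore share one site; the head-to-head
  geometry with two sites in a 118-bp gap yields two sites on each gene,
  as window coverage dictates.
* **Operon chaining** joins co-directional genes with intergenic gaps ≤ 100
  bp (configurable). The default reproduces the canonical three-gene-operon
  / divergent-pair / head-to-head layouts: the 29-bp divergent gap is
  handled by site *sharing*, not chaining, and 118 bp correctly separates
  the head-to-head pair.
* **Consistency check.** Support for a candidate transcription unit counts
  *other* genomes in which an orthologue of at least one member gene
  directly carries a candidate site; self-support would make cross-genome
  comparison circular. The default K = 2 is configurable and recorded in
  the output; how many genomes the historical procedure required is not
  printed anywhere, so K is an explicit knob rather than a buried constant.
* **Ambiguity codes.** `N` is legal in genome sequence; windows overlapping
  `N` score −∞ and can never be reported, which gives defined behaviour on
  draft genomes.

`assemble_regulon()` composes scan → assign → chain → filter, then expands
membership: every gene of a retained, site-bearing unit is a member,
`direct_site` if the gene itself has an assigned site, `operon_inherited`
otherwise.

## Expression analysis

Per spot, `m = log2(test/ref)` and `a = (1/2) log2(test·ref)`; channels are
labelled by sample, so dye-swap symmetry is definitional and the dye
orientation column exists for bias modelling, not sign fixing.

* **Normalization.** Per-array LOWESS of m on a, subtracted; span 0.3
  follows common two-colour practice. Arrays under 20 spots are skipped
  with a warning.
* **Replicate significance.** The array platform modelled here provides 8
  technical replicate spots per gene (4 spots × 2 dye-swapped arrays). A
  gene is considered only if ≥ 6 of its spots are individually significant
  at α = 0.05. How the original platform software defined spot-level
  significance is not printed; here each spot's normalized m is tested
  against the array-wide null spread (MAD about zero, two-sided normal
  test), and a per-gene one-sample t-test p-value is reported alongside.
  The reading — replicate m values per gene — and all constants (α,
  6-of-8, the per-array null) are configurable.
* **Cut-offs are inclusive**: `m ≥ 1.0` is up, `m ≤ −1.0` is down. The
  published gene with m printed exactly as 1 is counted among the
  up-regulated set, which fixes the convention.
* **No multiple-testing correction by default**, matching the per-test 5%
  rule; `adjust = "BH"` enables Benjamini–Hochberg on the gene-level p.
* **qPCR.** The relative change is `2^−ΔCP`, ΔCP the difference of mean
  crossing points (test − control); it is multiplicative across shared
  references, and ΔCP = −3 is an eight-fold change.
* **Integration.** `integrate_targets()` labels genes `direct` (up and in a
  site-bearing unit), `indirect` (up without a site), `down`, or
  `site_without_expression_support` — the pattern shown by the
  alcohol-dehydrogenase locus, whose conserved candidate site is distal to
  the promoter and not bound in vitro.

## Regulatory geometry

Site-promoter classification is a three-way partition: `overlaps_core`
(site overlaps the −10, with or without the −35), `overlaps_minus35`, else
`distal` with a strand-aware distance from the site's downstream edge to
the transcription start (negative and flagged when the site lies downstream
of it). Any non-overlapping placement is treated as
repression-incompatible; no intermediate class exists, because the
repression mechanism modelled is steric occlusion of the core promoter.
Leaderless transcripts are detected as `tss == first base of the start
codon`, strand-aware.

EMSA probes are 40-mers with the 21-mer site centred in native flanks
(left 10 / right 9; "centred" leaves one nt of freedom and the split is
fixed for determinism). Transition mutagenesis (A↔G, C↔T) is an involution;
mutating the motif drives its Z-score below the training threshold, while
flank-only mutation leaves the embedded site untouched — mirroring the
binding/no-binding contrast seen in vitro. The default mutates every motif
position; which subset the original assays mutated is not documented, so
the position set is an argument.

## The synthetic generator: what it emulates, and what it does not

`simulate_panel()` builds the study conditions the analysis assumes:
10 genomes, 80% carrying the regulon; order-1 Markov background at 54% GC
(high-GC actinobacterial composition); the regulon laid out as in the
*C. glutamicum* genome (three-gene operon in divergence with a singleton
across a 29-bp gap sharing one site; a second three-gene operon; a
head-to-head pair with two sites in a 118-bp gap); one site per unit;
orthologous gene families linking the panel; optional decoy sites.

Three generator decisions deserve justification:

* **Planted sites are sampled from the motif model conditional on scoring
  at or above its threshold** (rejection sampling, ~8% rejection for the
  canonical model). Real training sites are, by construction, detectable at
  the training-minimum threshold; unconditioned sampling would plant
  "sites" the study's own scanner could never see and conflate generator
  mismatch with pipeline error.
* **Background genes are co-directional**, so each intergenic gap belongs
  to exactly one upstream window. With alternating strands every decoy
  becomes a shared divergent site spanning two gene families, which
  double-counts consistency support for reasons of layout rather than
  biology.
* **Decoys are planted one per background family, each in a single random
  genome.** A decoy recurring in front of orthologues in several genomes is
  precisely what the consistency check is designed to *keep*; only
  uncorrelated false positives measure its rejection behaviour.

Expression simulation plants lognormal spot intensities around true folds
with per-channel noise (sd 0.25 on the log2 scale by default), dye-swap
array structure, and an optional intensity-dependent dye-bias function;
qPCR simulation shifts crossing points by −log2(fold) with additive noise
(sd 0.2 cycles).

**What passing the benchmark does not show.** The background is a
stationary Markov chain — no repeats, no skew, no real intergenic grammar —
so false-positive rates on real genomes will be higher than on the panel.
Gene content is identical across genomes (no gain/loss, no paralogy), so
the orthology table is cleaner than any real one. Spot noise is iid
lognormal with a smooth bias; real arrays add spatial artifacts and
saturation. The benchmark therefore validates the *machinery* — coordinate
arithmetic, strand handling, filter semantics, estimator calibration — not
the field error rates of motif scanning.

## Problem sizes and runtime envelope

The test-suite and acceptance computations use: a 10-genome panel of ~37 kb
genomes (30 background genes + the 9-gene regulon cassette), 100 microarray
simulations of 200 genes × 8 spots, and 1000 qPCR simulations — sizes
chosen so the full validation runs in well under two minutes on one core
while keeping Monte-Carlo error on the reported rates below about one
percentage point.

## Known limitations

* Consistency support is computed at gene level from direct site
  assignments; regulatory rewiring in which orthologues are regulated
  through different operon members reduces measured support.
* Z-scores carry no p-value calibration and no dinucleotide background
  correction; thresholds are training-set-relative by design.
* Promoter elements (−10/−35, TSS) are user inputs; the package classifies
  geometry but never predicts promoters from sequence.
* The discovery sampler finds a single shared motif of fixed width;
  variable-width or multi-motif search is out of scope.
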