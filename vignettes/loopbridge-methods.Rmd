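---
title: "loopbridge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loopbridge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopbridge)
```

This vignette explains what loopbridge computes, the assumptions behind each
step, the knobs that matter, and the deliberate design choices made where
the underlying procedures are conventionally underspecified. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The analysis in one paragraph

Promoter-capture Hi-C yields, per condition, a set of interactions between
a probe-captured promoter fragment (the *bait*) and a distal fragment (the
*other end*), each carrying a raw read count and a CHiCAGO-style confidence
score. loopbridge filters these to high-confidence cis loops, normalizes
counts to CPM so conditions with different sequencing depth are comparable,
classifies the other end against regulatory element catalogs, and then asks
three quantitative questions: per gene, did mean promoter–enhancer (PE)
looping strength increase between conditions (Δcounts)? Across genes, does
PE loop strength correlate with expression (Spearman)? Across a patient
cohort, does a composite TF-activity score stratify survival (Kaplan–Meier
with log-rank)?

## Coordinates and interval algebra

All intervals are 0-based, half-open `[start, end)` — the BED convention —
everywhere inside the package. Inputs in 1-based coordinates are the
caller's responsibility; no auto-detection is attempted, because silent
coordinate guessing is the classic source of off-by-one artifacts.
Consequences of half-openness are applied consistently: book-ended
intervals (`[a,b)` + `[b,c)`) do **not** overlap, but `merge_intervals()`
fuses them (matching the common bed-merge default, and making the union of
half-open spans well-defined); virtual 4C bins are half-open with boundary
midpoints assigned to the bin starting at the boundary.

Overlap requirements default to 1 bp (`min_overlap = 1`) for every
"anchored at" / "overlaps" test. No reciprocal-overlap rule is imposed —
the simplest defensible reading — and the threshold is exposed wherever it
is used.

The interval engine (merge, pairwise-intersection co-localization,
membership queries) delegates to GenomicRanges/IRanges internally; the test
suite verifies it against independent brute-force oracles (coverage
vectors, all-pairs intersection, linear scans).

## Element catalogs and loop classes

Active enhancers are H3K27ac peaks co-localized with Med1; insulators are
CTCF peaks co-localized with Rad21 (cohesin). Promoters are, by default,
symmetric windows of ±2 kb around the TSS (`flank = 2000`), deliberately
ignoring strand; a `hallmark` mode using Pol II ∩ H3K4me3 is provided,
since either definition is defensible and data sets differ in which is
available. 2 kb is the conventional promoter-proximal window; it is a
configuration knob, not a constant.

An anchor overlapping several catalogs gets exactly one class via the fixed
precedence **promoter > enhancer > insulator > other**. Capture design
biases anchors promoter-ward, so promoter is the natural first claim; the
precedence makes class fractions disjoint and tallies sum to exactly 1,
with the residual class (`P_OTHER`) explicit rather than implied.

For TF-anchored loop tallies, "anchored at a TF peak" defaults to *either*
anchor overlapping a peak (the most inclusive reading); an
`other_end_only` mode is provided.

## Loop processing choices

* **Score cutoff.** Strictly greater than 5, per the standard
  high-confidence convention for CHiCAGO scores; a score of exactly 5.0 is
  excluded. Inter-chromosomal loops are removed by default (`cis_only`).
* **Replicate collapsing before normalization.** Duplicate (bait, other
  end) records are fused — counts summed, score maximum — on raw counts,
  and CPM is applied afterwards, mirroring the merge-then-normalize order
  of standard processing.
* **CPM.** `count / library_size × 10⁶`, with the library size always the
  sum of counts of the *current* set (recomputed after filtering). The
  normalized set totals 10⁶ by construction and relative ratios between
  loops are untouched.
* **Loop distance.** Distance between anchor midpoints
  (`floor((start+end)/2)`), symmetric and stable under deduplication;
  undefined (NA) for trans pairs.
* **Virtual 4C.** Bins of 1.5 kb by default — the working resolution of
  4-cutter capture maps — tiled from the region start; each loop of the
  viewpoint gene contributes its (CPM) count to the bin containing its
  other-end midpoint. Per-promoter strength for comparisons is exposed both
  per interaction and summed per gene; per-interaction is the default.

## Δcounts: differential PE looping

For gene *g* and condition *c*, the qualifying loops are those baited at
*g* whose other end overlaps the active-enhancer catalog, in a set that has
already been confidence-filtered and CPM-normalized. Then

> Δcounts(g) = mean CPM count over qualifying loops in A − same in B,

with direction *increased* iff Δcounts > threshold (default 0, i.e. any
positive difference — no minimum effect size is imposed) and
*not evaluable* iff either condition has no qualifying loop. "Has
significant PE loops in both conditions" is operationalized as ≥ 1
qualifying loop per condition after the score cutoff, applied per
condition (not to a union set). The cohort summary reports
`n_increased / n_evaluable`. No per-gene significance test is attached to
Δcounts — it is a descriptive effect measure.

A property worth knowing: because means are compared on CPM scales, a
*genome-wide* shift in looping partially self-normalizes. If every gene's
PE loops rise 10-fold in one condition, that condition's library rises
almost as much, and the realized CPM ratio is far smaller than 10. With
remodeling confined to a subset of genes (the regime the method is meant
for, and the generator's default of 30%), the compression is mild; the
package's tests exercise both regimes.

## Motif-analysis region sets

The region sets handed to external motif-enrichment software are built in
three stages of interval algebra over the oncogene-restricted loop set:
(1) merge the loop anchor spans with open-chromatin (ATAC) peaks; (2) keep
merged intervals overlapping a ±2 kb window around a differentially
expressed oncogene TSS; (3) keep intervals overlapping H3K27ac peaks
(promoter/enhancer variant) or CTCF∩Rad21 sites (insulator variant).
Stages 2–3 *filter whole stage-1 intervals by association* rather than
trimming to the intersection — "merged with" is read as co-selection — and
a `restrict = "intersect"` switch provides the trimming alternative, since
the arrow semantics of such workflows are genuinely ambiguous. An empty
result at any stage returns empty with a warning naming the stage.

## Cohort scoring and survival

* **Z-scores** use the sample SD (n−1); a zero-variance gene row is an
  error naming the gene, not a silent NaN.
* **Activity score** is the unweighted mean of subunit Z-scores per sample
  (default subunit set: the seven major AP-1 subunits). Averaging a family
  sidesteps subunit-level compensation that blurs single-gene comparisons.
  The score is invariant to adding non-subunit rows to the matrix.
* **Median split**: *high* iff score strictly above the median; exact ties
  go to *low* (deterministic; documented rather than randomized).
* **Quartiles** are rank-based (equal count), cut at ranks `⌈n·j/k⌉` with
  stable tie order, rather than value-based — robust to skewed score
  distributions, and `Q4` always holds the highest scores. Quantiles are
  computed on the activity scores by default; raw mean intensity is equally
  accepted as input.
* **Kaplan–Meier / log-rank** use the standard product-limit estimator and
  two-group log-rank statistic `(Σ(O−E))²/ΣV` (1-df chi-square), via the
  `survival` package, with subjects censored at *t* counted at risk at
  *t*. The log-rank test is this package's choice of significance test for
  the survival separation — a standard reconstruction, since group
  comparisons of KM curves conventionally leave the test unnamed.
* **Spearman correlation** of per-gene loop strength with expression uses
  average-rank ties and the large-sample t approximation for p.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated by
recovering planted truth. Its defaults are the study conditions under which
the package's acceptance checks run: 300 captured genes on four 5-Mb
chromosomes (≥ 20 kb TSS spacing), ~56% flagged oncogenes (the share of
oncogene baits on a mixed oncogene/highly-expressed capture panel), 40% DE
genes (half up, half down at log2FC 2), three enhancer sites and one
insulator site per gene, per-gene Gamma-distributed base loop rates with
mean 50 (shape 10, so strength varies continuously across genes), Poisson
counts, 90% of loops clearing the score-5 cutoff, a planted remodeling
fraction of 0.30 at fold change 2, a planted loop–expression Spearman ρ of
0.3 via a Gaussian copula, and a 400-patient cohort with hazard ratio 2 for
above-median latent activity and ~20% independent exponential censoring.

Design decisions inside the generator:

* **Two-sided direction planting.** The remodeling fraction controls the
  share of genes whose PE rates are multiplied by the fold change in
  condition A; the *complement is planted decreased* (divided by the fold
  change). If non-remodeled genes had exactly equal means, their direction
  call would be a coin flip and "recovery of the planted direction" would
  be meaningless; planting both sides makes every gene's truth
  well-defined.
* **Exact Spearman planting.** The copula's latent Pearson correlation is
  `2·sin(π·ρ/6)`, so the planted *rank* correlation equals ρ exactly. The
  gene-level residual is shared between conditions (a gene keeps its
  baseline identity); DE shifts apply to condition A only, so condition B
  carries the planted copula exactly while condition A shows the realistic
  attenuation caused by expression changes unrelated to looping.
* **Territorial site placement.** Enhancer and insulator sites are kept
  clear of every promoter window and of each other (margin = anchor
  half-width + peak width), and same-type sites do not overlap. Each
  planted loop therefore classifies as its wired type, co-localization at
  probability 0 is exactly empty, and planted class proportions are
  recoverable from tallies. The cost is a modest, deterministic thinning
  of sites that land in another element's territory.
* **H3K27ac at promoters.** Acetylation marks active promoters as well as
  enhancers; Med1 co-localization is what restricts the enhancer catalog
  to enhancer sites.
* **Poisson counts** by default (no overdispersion parameter is needed for
  the planted-effect checks); the Gamma gene-level rate already induces
  extra-Poisson variation marginally.
* **Substreams.** One master seed feeds fixed per-stream seeds (genome,
  peaks, interactions, expression, cohort), so adding a generator never
  perturbs existing streams, and any artifact regenerates byte-identically
  from (config, seed).

What the generator does **not** emulate: genomic distance decay of contact
frequency, sequence content, peak-width variation, overdispersed
(negative-binomial) counts, correlated censoring, or batch structure.
Passing tests on this generator therefore demonstrate the *correctness of
the computations* under known structure, not robustness to every artifact
of real sequencing data.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen scales: interval-algebra
oracle checks at 1,000 random intervals; Δcounts recovery at the default
300 genes; Spearman recovery at 1,000 genes over 100 seeds; survival
size/power at 500 simulated cohorts of 400 patients. These sizes make the
binomial/Monte-Carlo error of each check small relative to its acceptance
band (e.g. the recovered remodeling fraction is compared within ±0.05 of
0.30, the mean Spearman estimate within ±0.06 of 0.3, the type-I error
within ±0.02 of 0.05, power ≥ 0.8).

Degenerate inputs are defined, not guessed: empty interaction sets cannot
be CPM-normalized or tallied (error), an unknown gene yields an empty loop
collection (not an error), an all-tied score vector median-splits to all
*low* with a warning, and a zero-variance expression row is an error naming
the offending gene.

## Known limitations

* Δcounts carries no significance test; with one qualifying loop per
  condition the "mean" is a single noisy count.
* CPM comparison partially absorbs genome-wide remodeling (see above);
  spike-in or copy-number-aware normalization is out of scope.
* The element catalogs are binary (peak overlap), ignoring signal
  strength; precedence resolves multi-class anchors deterministically
  rather than probabilistically.
* The survival module implements two-group log-rank and KM only — no Cox
  regression or covariate adjustment.
* Readers handle the text formats defined here (BED3+, the 8/9-column
  interaction dialect, TSV tables); binary formats (bigWig, BAM) are out
  of scope.
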