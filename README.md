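# loopbridge

Integrative analysis of promoter-capture Hi-C (pcHiC) chromatin loops in a
two-condition design — for example a cancer cell line against a matched
non-cancerous control — together with the downstream question such data are
collected to answer: does a transcription factor's occupancy at loop anchors
track oncogenic transcription, and does its composite expression level
stratify patient survival?

pcHiC enriches ligation products anchored at probe-captured promoter
fragments ("baits"), yielding promoter-centric interaction maps in which the
non-bait anchor ("other end") may fall on another promoter, an active
enhancer, an insulator, or none of these. loopbridge takes the called
interactions (with read counts and CHiCAGO-style confidence scores), hallmark
ChIP/ATAC peak sets, a TSS annotation, expression matrices and a clinical
cohort, and provides every step between them:

* **Loop processing** — confidence filtering (score strictly `> 5`,
  inter-chromosomal loops removed), replicate collapsing, and CPM
  normalization (`count / library size × 10⁶`) so looping strength is
  comparable across conditions.
* **Element catalogs and loop typing** — active enhancers as
  H3K27ac ∩ Med1 co-localized peaks, insulators as CTCF ∩ Rad21, promoters
  as symmetric TSS windows (or Pol II ∩ H3K4me3); loops classified
  PP / PE / P-ins / P-other from the other end with fixed precedence, and
  loop-type tallies for TF-anchored subsets.
* **Differential promoter–enhancer looping** — per gene, the mean
  CPM-normalized count over enhancer-overlapping loops in each condition and
  their difference, `Δcounts = mean_A − mean_B`; a gene is *increased* when
  `Δcounts > 0` and *evaluable* when it has qualifying PE loops in both
  conditions. The cohort summary reports `n_increased / n_evaluable`.
* **Virtual 4C** — all contacts of one viewpoint promoter binned along the
  chromosome (1.5 kb bins by default) as a bedGraph-like track.
* **Motif region sets** — the staged interval algebra (loop anchors ∪ ATAC
  peaks, restricted to DE-oncogene promoter associations, then to
  acetylated or insulator regions) that feeds external motif software.
* **Cohort scoring and survival** — per-sample activity score as the mean of
  row Z-scores over a subunit set (default the seven AP-1 subunits JUN,
  JUNB, JUND, FOS, FOSB, FOSL1, FOSL2), median-split and quartile
  stratification, Kaplan–Meier curves `S(t) = Π (1 − dᵢ/nᵢ)` and the
  two-group log-rank test; Spearman correlation of per-gene loop strength
  with expression.
* **qPCR closed forms** — ChIP-qPCR percent input `100 × 2^(−ΔCt)` and
  relative nascent-transcript abundance `2^(−ΔΔCt)`.
* **A seeded synthetic-data generator** — every input above with *planted*
  effects (remodeling fraction, fold change, loop–expression correlation,
  hazard ratio), so the whole pipeline is validated by recovering known
  truth.

## Worked example

The default configuration simulates the study conditions: 300 captured
genes, PE loop counts with base mean 50, 30% of genes planted with 2-fold
increased PE looping in condition A, a planted loop–expression Spearman
correlation of 0.3, and a 400-patient cohort with hazard ratio 2 for the
high-activity half.

```r
library(loopbridge)
report <- run_pipeline(default_pipeline_config(seed = 1))
report
#> loopbridge run report
#>   confident loops: A = 987 , B = 976
#>   remodeling: 47/169 genes increased (fraction 0.278)
#>   loop~expression Spearman rho: A = 0.131 , B = 0.244
#>   log-rank high vs low activity: chisq = 17.06 , p = 3.62e-05
```

Reading the report: of 1084 simulated loops per condition, 987 and 976
survive the score cutoff; among the evaluable *oncogenes* 27.8% are called
increased, recovering the planted 30% (over all 300 genes the recovered
fraction at this seed is 0.271); the loop-strength/expression correlation is
positive in both conditions (condition A is attenuated by the planted
differential-expression shifts riding on top of the copula); and the
high-activity half of the cohort dies significantly faster (log-rank
p ≈ 4 × 10⁻⁵, planted hazard ratio 2).

Individual stages are plain functions on plain containers:

```r
cfg    <- simulation_config(seed = 1)
genome <- simulate_genome(cfg)
peaks  <- simulate_peaks(cfg, genome)
loops  <- simulate_interactions(cfg, genome, peaks)

iset  <- cpm_normalize(filter_confident(loops$a))
track <- virtual_4c(iset, "g0001", "chr1:109721-169721", bin_size = 1500)
track[track$signal > 0, ]
#>   chrom  start    end   signal
#> 8  chr1 120221 121721 1824.426
```

The gene's contacts concentrate in the bin containing its planted enhancer,
~18 kb upstream of the TSS at chr1:139,721. And the bench-side arithmetic:

```r
percent_input(ct_ip = 25, ct_input = 24, input_dilution_factor = 64)
#> [1] 0.78125
```

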