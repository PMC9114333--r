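---
title: "Methods: TAD-constrained correlation maps and accessibility-based prognosis"
author: "atacmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAD-constrained correlation maps and accessibility-based prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacmap)
```

## The analysis

`atacmap` integrates three data layers over a tumour cohort: ATAC-seq peak
accessibility (a peak-by-sample count matrix over a consensus peak set),
RNA-seq gene expression on the subset of samples with usable RNA, and
clinical metadata including overall survival in months. The package
answers two questions: *which genes does each accessible region plausibly
regulate*, and *how much prognostic information does chromatin
accessibility carry*.

### Consensus peaks and normalization

Per-sample peak calls are merged into a consensus set: any two peaks whose
overlap covers at least 50% of the shorter peak are replaced by their
spanning interval, transitively, iterated to a fixed point
(`mergeConsensus()`). This definition is deterministic and independent of
the order in which the per-sample sets are supplied — properties the
common "merge anything that touches" heuristics lack. Peaks on chrX, chrY
and chrM are removed, since mixed-gender cohorts confound accessibility
with genotype there.

Counts are corrected for sequencing depth with median-of-ratios size
factors (the estimator used throughout differential-expression analysis),
rescaled to geometric mean one, and transformed as
`log2(count / sizefactor + 1)` (`logNormalize()`). This transform is the
package's fully specified stand-in for regularized-log transforms: it is
monotone, exactly invertible, and reproduces the "library size + log2"
contract without depending on another package's shrinkage details. The
pseudocount of 1 compresses differences among features with single-digit
counts, which is intended: such features are mostly noise at typical
ATAC depths.

### The TAD-constrained correlation map

The conventional shortcut assigns every peak to its nearest gene. The
package instead treats chromosome spatial structure as the gate: a peak
may be paired only with genes in the same topologically associating
domain (TAD), on the argument that regulatory contacts rarely cross TAD
boundaries. A peak belongs to a TAD when at least 90% of the peak's
length falls inside it (`assignToTAD()`); peaks straddling boundaries are
deliberately left unassigned rather than being forced into a domain.

For every (peak, gene-in-same-TAD) pair the Pearson correlation of
log-normalized accessibility and expression is computed across the
RNA-profiled samples (`peakGeneCorrelations()`). Pairs with `r^2 >= 0.6`
(sign tracked separately) are called links. The same screen against
survival months (`peakSurvivalCorrelations()`) produces the univariate
prognostic associations; by default it uses every sample with
accessibility data, since survival needs no RNA. Each pair is annotated
with whether its gene is also the peak's nearest gene, where "nearest"
means smallest distance from the peak midpoint to a transcription start
site; strand determines which end of the gene is the TSS, and ties go to
the lexicographically smaller gene id so results are reproducible.

Two choices deserve emphasis. The `r^2` threshold is inclusive
(`>= 0.6`), and it is applied to the squared coefficient, so strong
negative correlations pass the gate and are counted in the sign
fractions. And a peak correlated with several genes contributes one link
per gene: the map is a relation, not a function.

### The prognostic modelling chain

Modelling proceeds in stages, each cheap to audit:

1. **Variance filter.** Features with population variance (divisor *n*)
   at or below 0.45 on the log scale are removed. The threshold is the
   pipeline default and matches common variance-filter practice on
   regularized-log ATAC data.
2. **Importance ranking.** A bagged random-forest regression of survival
   on the remaining peaks — 1000 trees, each grown on a with-replacement
   sample of 90% of the cohort, all features eligible at every split —
   is scored out of bag, and features are ranked by permutation
   importance (`rfImportanceRanking()`). The default estimator permutes
   each feature once per tree on that tree's out-of-bag samples and
   averages the accuracy loss (the classical forest permutation
   importance, computed natively by ranger in one pass). An
   ensemble-level variant — permute the feature's whole column several
   times and measure the drop in ensemble out-of-bag R² — is available
   via `importanceMethod = "ensemble"`; it estimates the same quantity
   with far fewer permutations per feature and is priced accordingly
   (one ensemble prediction per feature and repetition), so it is
   practical only for small panels. The two agree in ranking on planted
   signals; the tree-level estimator is the default at genome scale.
3. **Top-k selection.** The 20 highest-ranked peaks enter the model
   stage; ties break lexicographically.
4. **Elastic net with LOOCV.** `elasticNetFit()` minimizes
   `(1/2n)·RSS + λ(α‖β‖₁ + (1−α)/2‖β‖₂²)` over the mixing grid
   `α ∈ {0, 0.1, …, 1}` (11 values) and a per-α path of 100 log-spaced
   λ values from the smallest λ that zeroes every slope down to `1e-4`
   of it. The pair (α, λ) maximizing the leave-one-out predicted R²,
   `1 − Σ(yᵢ − ŷ₋ᵢ)² / Σ(yᵢ − ȳ)²`, is selected. Features are
   standardized internally; coefficients are reported on the original
   scale. Ties on the LOOCV surface resolve to the larger λ (the
   sparser model).
5. **Compact model.** A plain least-squares model on six peaks — those
   with nonzero elastic-net coefficients, falling back to the six most
   important peaks when the net selects none; the report records which
   rule fired. Both the in-sample R² and the leave-one-out R² (via the
   hat matrix) are reported, since with ~38 samples the two can differ
   substantially.
6. **Three-way comparison.** The same elastic-net protocol runs on the
   selected peaks, on encoded clinical covariates (age numeric; gender,
   IDH1, stage binary; grade ordinal II=2/III=3/IV=4; pathology one-hot
   dropping the first level), and on their union. Samples with
   undetermined IDH1 status are excluded from *all three* models so the
   comparison is made on one shared sample set.

Survival is treated as a fully observed continuous response; no censoring
model is attached, and consequently no Kaplan–Meier or Cox machinery
appears anywhere. This mirrors how the response is defined (months from
resection to death) and keeps every model a regression.

### Differential accessibility

Each (grade, stage) group is compared against all remaining samples with
a two-sided Welch t-test per peak on the log-normalized values
(`groupVsRestTest()`); the effect size is the difference of group means,
which on this scale is a log2 fold change. A fully specified two-sample
test was chosen over negative-binomial Wald machinery because the
downstream claims are threshold-gated set constructions — peaks with
`log2FC >= 0.3` and Benjamini–Hochberg `FDR <= 0.05`, both bounds
inclusive, enrichment direction only — and the Welch test on normalized
values makes the null calibration directly checkable (the test suite
verifies near-uniform null p-values and the empirical false-discovery
fraction). The absolute-fold-change variant is available via
`direction = "absolute"`.

Per-sample "total open peaks" counts features with length-normalized
abundance (TPM over peak lengths) strictly above 10; a counts-per-million
variant without length correction is provided since conventions differ.
Group totals are compared by fixed-effects one-way ANOVA, and paired
resections (same patient, primary then recurrent) and pre/post-radiation
culture pairs are summarized as post-minus-pre deltas.

## The synthetic cohort generator

`simulationConfig()` fixes every parameter of a generative model shaped
like the study the package targets; all randomness is a pure function of
the seed.

* **Genome.** TADs of 1 Mb tile synthetic chromosomes; 6 genes and 10
  peaks per TAD by default. A configurable fraction of peaks (5%) is
  centred on TAD boundaries so that no TAD contains 90% of them — these
  exercise the containment gate and stay out of the correlation map.
* **Cohort.** Group sizes default to 7/9/9/13 across grade II, III, IV
  primary and IV recurrent (38 samples); survival is lognormal with
  grade-dependent location (medians ≈ 60, 49, 13 and 7 months) and
  sdlog 0.5; IDH1 mutation probability falls with grade (0.9/0.8/0.3)
  with a 10% undetermined fraction; 16 samples carry RNA; three patients
  contribute a primary and a recurrent specimen.
* **Counts.** Latent log2 accessibility is baseline (uniform 5–9) plus
  N(0, 0.7) noise; counts are negative binomial (dispersion 0.1) with
  lognormal library sizes (sdlog 0.3). Planted peak–gene links give the
  peak a boosted latent sd (1.8) and let the linked gene's expression
  track the peak's latent deviation; planted survival drivers add
  `β · z(survival)` to the peak's latent mean. 90% of links and drivers
  are positive, mirroring the positive-dominated maps the analysis
  expects; 10% of links target the peak's nearest gene, the rest a
  distal same-TAD gene. Each linked gene is distinct.
* **Calibration.** The free noise parameters of planted effects are not
  set by hand: the generator computes the exact mean and variance of
  `log2(NB + 1)` from the negative-binomial pmf, averages them over the
  latent normal by Gauss–Hermite quadrature, and solves for the gene
  noise (links) and the slope β (drivers, by fixed point) such that the
  *expected observed* Pearson correlation — after counting noise and the
  pseudocount's compression — equals the configured targets (0.9 for
  both). The test suite verifies the realized mean |r| lands within
  ±0.05 of the target.
* **Dropout.** Each recurrent sample silences a random 30% of peaks
  (mean scaled to near zero); radiation pairs silence 30% in the post
  column only. Peaks carrying planted links or survival effects are
  exempt from dropout so the exported ground truth remains coherent —
  dropout models background chromatin closing, not the removal of the
  planted biology. Both recurrence and radiation effects are modelled
  as dropout only; no mechanistic DNA-damage model is attempted.

What the generator does *not* emulate: genomic sequence content, GC or
mappability biases, peak-width variation tied to signal strength,
correlated peak modules beyond the planted links, batch structure, or
censored survival. Tests passing on this generator therefore demonstrate
that the pipeline's inference machinery recovers known structure under
its own statistical assumptions — not that those assumptions hold in any
particular real dataset.

## Numerical and design notes

* Coordinates are BED-convention 0-based half-open on disk and in
  regenerated peak ids (`chr1:100-250`), 1-based closed inside R
  (GRanges); the readers and writers convert exactly.
* Reciprocal-overlap merging uses the fraction of the *shorter* interval
  and merges transitively: if A qualifies with B and B with C, all three
  span together even when A and C alone would not qualify. The
  brute-force oracle in the test suite implements the same definition
  independently and the two agree on random instances.
* `pearsonR()` returns `NA` for zero-variance input rather than a silent
  zero; degenerate peaks are excluded from maps, never counted as null
  correlations. Welch tests on zero-variance pairs report p = 1 when the
  means agree and p = 0 when they differ, flagged either way.
* The survival screen defaults to all samples with accessibility data
  (survival needs no RNA); restricting it to the RNA subset is a
  one-line subset by the caller.
* Statistical power of the differential gate at its defaults is governed
  by the BH threshold, which scales with the fraction of truly shifted
  peaks: a 1.0-log2 shift at σ = 0.5 and n = 8 vs 8 gives per-peak power
  0.96 unadjusted, but only ~0.46 when 5% of a 500-peak panel shifts.
  The power checks in the test suite therefore use a panel in which most
  peaks shift, the regime the global-closing contrasts actually occupy.
* Problem sizes in the test suite (e.g. 8000 null peaks and 20 seeds for
  the modelling-chain recovery check, 200 planted links against 2000
  null pairs for the correlation map) were chosen as the smallest
  configurations at which the recovery statements are sharp; the
  generator scales to larger genomes by configuration.

## Known limitations

* Survival censoring is ignored by design; cohorts with many survivors
  at last follow-up will bias every survival model optimistic.
* The elastic-net LOOCV surface can be flat near its maximum in small
  cohorts; the deterministic tie-break (larger λ, then smaller α) picks
  one representative but neighbouring models may predict equally well.
* TAD annotations are consumed as given; the package neither infers
  domains nor models contacts within them beyond the binary gate.
* The Welch stand-in tests normalized means, not counts; at very low
  counts its normality assumption is the binding constraint, which is
  why the variance filter precedes every model stage.
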