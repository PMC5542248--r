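---
title: "Methods: the peaks transformation and the OCRI2 risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the peaks transformation and the OCRI2 risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocri2)
```

## The problem

DNA-image cytometry of brushed oral mucosa yields, for each subject, a
sample of DNA-index (DI) values: per-cell ratios of integrated nuclear
DNA staining to a diploid reference. Healthy mucosa is dominated by
diploid cells (DI near 1) with a small tetraploid/G2 fraction (DI near
2). Malignancy-associated genomic instability produces aneuploid
populations at other DI values; a cell with DI >= 2.3 is conventionally
called aneuploid. The clinical question this package addresses is
quantitative: given the DI distribution of an oral leukoplakia (OLK)
lesion, how likely is it to be — or to become — an oral squamous cell
carcinoma (OSCC)?

Two scoring approaches are implemented side by side. The *traditional
method* counts aneuploid cells and calls a case negative (0), atypical
(1–5) or positive (>5). The *peaks method* summarises the whole DI
distribution and feeds it to a classifier, whose predicted probability
of OSCC is the oral cancer risk index **OCRI2**, a number between 0
and 1 with 0.5 as the (deliberately simple) high/low-risk cutoff.

## The peaks transformation

Each case is reduced to a 10-component integer vector in three steps.

1. **Density estimation** (`estimate_density`). A Gaussian kernel
   density estimate of the case's DI values, computed with
   `stats::density()`: Silverman's rule-of-thumb bandwidth
   (`bw.nrd0`, `h = 0.9 min(sd, IQR/1.349) n^{-1/5}`), 512 grid
   points, grid extended 3 bandwidths past the data range. All three
   settings are exposed in `density_config()`; a fixed bandwidth can
   replace the rule (and must, when a sample has zero spread, where
   the rule is undefined and the function refuses to guess).
2. **Peak detection** (`detect_peaks`). The first derivative is
   mimicked by lagged differences of the density values; a *peak* is a
   grid point where the differences change sign from positive to
   negative — the curve stops rising and starts falling. The first and
   last grid points are never peaks. On a discretised curve exact ties
   can form plateaus; a plateau preceded by a rise and followed by a
   fall counts as exactly one peak, placed at its first grid point.
   This is a deliberate, documented reading: "rising then falling" is
   taken to mean a true local maximum, which matches the expected
   two-peak signature of normal samples.
3. **Interval tallying** (`bin_peaks`). Peak locations are tallied
   into ten unit intervals centred on the ploidy numbers 1..10:
   [0.5, 1.5), [1.5, 2.5), …, with anything below 0.5 folded into the
   first interval and anything at or above 9.5 into the last.
   Boundaries are lower-closed half-open, so a peak at exactly 1.5
   lands in interval 2; the choice is arbitrary but deterministic and
   order-independent, and it keeps the tally total equal to the number
   of peaks.

`reconstruct_dataset()` applies this to a whole cohort, producing the
n-by-12 feature table (`V1..V10`, class label, case id) that every
model consumes. Normal cases put their peaks in intervals 1–2; OSCC
cases scatter peaks across the higher intervals.

A practical caveat worth stating: Silverman's rule under-smooths very
tight, large-n samples (the IQR term tracks the narrow diploid
population), which can fragment a mode into several micro-peaks. Those
micro-peaks still fall in the correct ploidy interval, so interval
counts — not peak counts per se — remain the meaningful feature, and
classification is unaffected. Tests that assert an exact number of
modes therefore pin the bandwidth explicitly.

## Classifiers and OCRI2

`tune_and_train()` implements one tuning protocol for all five
supported models: random forest (`rf`, the production model), a
radial-kernel SVM tuned on 70% of the cohort (`svm`), the same SVM
trained on 100% (`svmfull`), k-nearest neighbours (`knn`), and a
second, independently implemented probability forest (`cf`, backed by
`ranger`) kept as a cross-check baseline. Training always uses only
normal and OSCC rows — OLK rows are what the index is *for*, so they
are only ever scored, never fitted on.

The protocol: a stratified random split reserves
`optimization_fraction` (default 70%) of the cohort; on that part,
every hyperparameter candidate is evaluated by stratified 10-fold
cross-validation repeated 5 times (50 resample fits per candidate,
identical fold assignments across candidates); the best mean accuracy
wins, with exact ties broken toward the first candidate in grid order;
the winner is refit on the whole optimisation part. Default grids are
small and conventional: trees-per-forest fixed at 500 with
features-per-split in {2, 6, 10} for the forests, cost in
{0.25, 0.5, 1} for the SVMs, k in {5, 7, 9} for KNN on untransformed
counts. Every random draw derives from the single `seed` in
`model_spec()`, so a run is exactly reproducible.

**OCRI2** (`compute_ocri2`) is the fitted model's class-c probability:
for forests, the fraction of trees voting OSCC; for KNN, the neighbour
vote fraction; for the SVMs, the calibrated class probability. One
caveat is inherent to the SVM backend: libsvm's probability
calibration uses its own internal random generator, which R's seed
does not control across repeated fits in one session, so SVM
probabilities are reproducible across fresh sessions but only
approximately within one. The forests and KNN are bit-reproducible
everywhere, and the byte-identity guarantee the package tests is
stated for the production random-forest path.

`cross_examine()` runs the two-cohort protocol: tune and train on
cohort A, score all normal/OSCC rows of cohort B, tabulate the
confusion matrix (cancer = positive), sensitivity, specificity, PPV,
NPV and the rank (Mann–Whitney) AUC — then reverse the roles.

## Evaluation statistics

Confusion-matrix metrics use their textbook definitions, and a metric
whose denominator is empty (e.g. PPV with no positive calls) is
reported as `NA`, never coerced to 0. AUC is computed from ranks with
midrank tie handling, making it invariant under any strictly monotone
rescaling of the scores.

The follow-up comparison — did high-risk OLK transform more often than
low-risk OLK? — uses the two-sided Pearson chi-square with Yates
continuity correction on the 2x2 table, with the correction clamped at
|O − E| so an exactly independent table scores 0. The chi-square
approximation is kept even though one expected count is near 1, as the
continuity-corrected chi-square is this comparison's standard form; on
the published counts (4/11 high-risk vs 3/57 low-risk transformants)
it gives p = 0.0103, i.e. p = 0.01 at the printed precision. For the
three-category traditional comparison the Yates correction is
undefined (it exists only at 1 degree of freedom), so
`multi_group_chi_square()` uses the uncorrected Pearson statistic at
df = 2; all-zero categories are dropped first, so an empty category
does not alter the statistic.

## The synthetic cohort generator

No raw per-case DI data are publicly deposited for the cohorts this
methodology was developed on, so the package ships a simulator whose
defaults encode the documented distributional signatures, making every
pipeline stage testable end to end.

Each case draws 50–300 cells (uniform; a typical brush-biopsy yield)
from a Gaussian mixture truncated to DI > 0:

* **normal** — diploid (mean 1.0, sd 0.05, weight 0.93) plus
  tetraploid (mean 2.0, sd 0.10, weight 0.07);
* **oscc** — a heavier tetraploid fraction (weights 0.70/0.30) plus,
  in every case, three aneuploid components whose means are drawn
  uniformly over DI 2.5–8 (sd 0.15, total weight 0.5) — random
  placement per case reproduces the "spread across most intervals"
  signature rather than a fixed third mode;
* **olk_low / olk_high** — the same construction with carrier
  probabilities 0.1 and 0.6, modelling low- and high-risk leukoplakia.

Carrier status is drawn per case, not per cell, mimicking clonal
lesions. All parameters (components, prevalence, cell counts,
aneuploid placement) are arguments of `group_profile()`, and component
sds are order-of-magnitude choices typical of DNA-image cytometry
rather than estimates from any specific cohort.

What the simulator does *not* model: staining artifacts, debris,
imaging noise, inter-slide variability, or any overlap between the
class distributions beyond what the mixtures imply. Planted cohorts
are close to linearly separable in feature space; the near-perfect
cross-examination performance on them demonstrates that the pipeline
recovers planted structure faithfully, not that real cohorts separate
that cleanly.

## Numerical and design choices

* Problem sizes used by the shipped checks: 50 cases per class per
  cohort for cross-examination, 100 cases per group for signature
  rates, 1000 randomised curves for the peak-detector oracle — sizes
  at which the Monte-Carlo properties are stable across seeds while a
  full run stays comfortably interactive.
* The monotone-signal check (more aneuploid prevalence should not
  lower mean OCRI2 of simulated OSCC) is run with a variant OSCC
  profile sharing the normal base mixture, so the prevalence dial is
  the *only* difference between carriers and normals; with the default
  base, the tetraploid-weight difference alone already drives OCRI2
  high at every prevalence and the comparison would measure noise.
* "CF" is provided as a second forest implementation (`ranger`) rather
  than a conditional-inference forest, which is not available here;
  it is a baseline cross-check, not the production model, and is
  labelled accordingly.
* Group labels in files are full words (`normal/olk/oscc/unknown`);
  the single-character factor (`c/k/n`, plus the sentinel `u` for
  unknown, prediction-only cases) exists only inside feature tables.
* Pipeline artifacts embed the package version, the seed, and an
  FNV-1a digest of the full configuration as a leading comment line,
  so any output can be traced to the exact run that produced it.

## Limitations

The classifier operates on interval counts of density peaks — a
deliberately coarse summary that discards peak heights and cell
fractions; cases whose aneuploid populations are too small to raise a
density mode will score low. Thresholds (DI >= 2.3, the 0.5 risk
cutoff, the 0/1–5/>5 categories) are inherited conventions, not tuned
quantities. Follow-up handling is purely tabular (risk group x
transformation); no time-to-event modelling is attempted.
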