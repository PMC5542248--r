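# ocri2 — quantitative oral-cancer risk from DNA-index cytology

`ocri2` is an R package for quantitative cancer-risk assessment of oral
lesions from exfoliative-cytology DNA-index (DI) measurements. It is
aimed at researchers working on DNA-ploidy–based screening of oral
leukoplakia (OLK): given a sample of per-cell DI values for each
subject, the package turns each DI distribution into a compact ploidy
fingerprint, trains a classifier on normal vs carcinoma (OSCC)
fingerprints, and scores lesions with **OCRI2** — the predicted
probability, between 0 and 1, that a sample is OSCC — alongside the
rule-based *traditional* aneuploidy call.

## The method in brief

For a case with DI values $x_1,\dots,x_n$:

1. **Density.** A Gaussian KDE $\hat f_h$ is fit with Silverman's
   bandwidth $h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,n^{-1/5}$
   on a 512-point grid.
2. **Peaks.** Local maxima of $\hat f_h$ are found from sign changes of
   the lagged differences (rising → falling).
3. **Ploidy intervals.** Peak locations are tallied into ten unit
   intervals centred on DI $= 1,\dots,10$: $[0.5,1.5), [1.5,2.5),
   \dots$, with $<0.5$ folded into the first and $\ge 9.5$ into the
   last — giving the feature vector $V_1,\dots,V_{10}$.
4. **Risk.** A random forest (500 trees; features-per-split tuned over
   $\{2,6,10\}$ by 5×10-fold stratified CV on a 70% optimisation split)
   is trained on normal/OSCC rows; OCRI2 of a sample is the fraction of
   trees voting OSCC, and OCRI2 $\ge 0.5$ marks a high-risk lesion.

The traditional comparator counts aneuploid cells (DI $\ge 2.3$):
negative = 0, atypical = 1–5, positive = >5. Follow-up outcomes are
compared between risk groups with the Yates-corrected chi-square.
A synthetic cohort generator with documented ploidy mixtures
(diploid-dominated normals; dispersed aneuploid OSCC; intermediate OLK)
makes the full pipeline runnable and testable without patient data.

## Worked example

```r
library(ocri2)

# a synthetic study: 18 normals, 28 OLK, 41 OSCC
cohort   <- simulate_cohort(cohort_spec(
              c(normal = 18, olk_low = 14, olk_high = 14, oscc = 41),
              seed = 1))
features <- reconstruct_dataset(cohort)
head(as.data.frame(features), 3)
#>   V1 V2 V3 V4 V5 V6 V7 V8 V9 V10 label case_id
#> 1 16 17  0  0  0  0  0  0  0   0     n    N001
#> 2 13 24  0  0  0  0  0  0  0   0     n    N002
#> 3  9  4  0  0  0  0  0  0  0   0     n    N003

model <- tune_and_train(training_rows(features), model_spec("rf", seed = 1))
#> <ocri2_model> kind = rf | trained on 41 OSCC + 18 normal rows | seed 1
#> selected: mtry = 2

risk <- assess_risk(model, features)
risk[c(1, 20, 40, 60), ]
#>    case_id ocri2 risk_class
#> 1     N001 0.062        low
#> 20   KL002 0.062        low
#> 40   KH008 0.894       high
#> 60    C014 0.972       high
```

Normal cases keep their density peaks in the diploid/tetraploid
intervals ($V_1, V_2$) and score near 0; OSCC cases scatter peaks
across the aneuploid intervals and score near 1; the two OLK profiles
fall on either side of the 0.5 cutoff (here 18 of 28 OLK lesions are
called high-risk).

The follow-up comparison on the published transformation counts —
4 of 11 high-risk and 3 of 57 low-risk OLK progressing to carcinoma:

```r
tab <- matrix(c(4, 3, 7, 54), 2,
              dimnames = list(c("high", "low"),
                              c("transformed", "not_transformed")))
proportion_summary(tab)
#>   group transformed total   fraction percent
#> 1  high           4    11 0.36363636    36.4
#> 2   low           3    57 0.05263158     5.3
yates_chi_square(tab)
#> chi-square = 6.584, p = 0.0103
```

High-risk lesions transformed at 36.4% against 5.3%, a significant
difference (p = 0.01) — the quantitative index separates the OLK
population by real prospective risk.

A command-line interface wrapping each stage (`simulate`, `transform`,
`traditional`, `train`, `predict`, `crossexam`, `evaluate`,
`followup-test`, `pipeline`) ships at `inst/cli/ocri2.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ocri2.R", package="ocri2"))')" \
    followup-test --table '4,7;3,54'
```

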