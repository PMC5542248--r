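Package: ocri2
Title: Quantitative Oral Cancer Risk Prediction from DNA-Index Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative oral-cancer risk assessment from
    exfoliative-cytology DNA-index (DI) measurements. Implements the
    peaks transformation (kernel density estimation of a case's DI
    distribution, first-derivative peak detection, and tallying of peaks
    into ten ploidy intervals), a classifier harness (random forest and
    four baselines) that turns the resulting feature vectors into a
    0-to-1 cancer-risk probability (OCRI2), the rule-based traditional
    aneuploidy score (DI >= 2.3), cross-cohort evaluation statistics
    (confusion-matrix metrics, rank AUC, Yates-corrected chi-square for
    follow-up tables), and a synthetic cytometry cohort simulator so
    the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    class,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
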