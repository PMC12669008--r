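Package: nbthreshold
Title: Net-Benefit Decision Thresholds for Probabilistic Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing and evaluating decision thresholds of
    probabilistic binary classifiers in screening settings with strong class
    imbalance, such as AI readers in population mammography. Implements the
    net-benefit curve pair NetBenefit0/NetBenefit1 and their intersection rule
    for threshold selection, alongside the classical strategies it is compared
    against (Youden index, closest-to-(0,1) corner, fixed sensitivity or
    specificity, and decision-curve net benefit), plus ROC construction with
    trapezoidal AUC, diagnostic accuracy metrics, McNemar paired comparisons
    of thresholding strategies, BI-RADS binarization and CSV input/output,
    and a seedable generator of synthetic screening cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
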