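Package: melrank
Title: Diagnostic-Accuracy Measure Panels and Rank-Instability Analysis for
    Melanoma Classification Challenges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating and ranking computer systems that output a
    posterior probability of malignancy per skin lesion, in the style of open
    melanoma-classification challenges. Computes five diagnostic-accuracy
    measures (average precision, AUC of the ROC, and specificity at 95, 98 and
    99 percent sensitivity) plus the partial AUC over the high-sensitivity
    band; fits Gaussian discriminant classifiers (LDA, QDA and their diagonal
    naive-Bayes variants) with posterior-threshold and class-prior operating
    sweeps; stabilises high-sensitivity measures by stratified cross-validation
    and bootstrap; builds multi-measure leaderboards with competition ranking
    and Kendall tau-b rank-instability statistics; and generates seeded
    challenge-scale synthetic submissions and feature tables, including a
    25-system suite engineered to exhibit measure-dependent rank reversal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
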