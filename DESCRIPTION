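Package: jmipanel
Title: Gene Panel Discovery by Moderated Differential Expression and
    Joint Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid filter pipeline for two-class transcriptomic biomarker
    discovery. Genes are first screened by a two-group linear model with
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg adjustment
    (the limma-style differential-expression filter), then a compact,
    minimally redundant panel is chosen by greedy forward selection under the
    joint mutual information (JMI) criterion, with minimum-redundancy
    maximum-relevance (mRMR) as a comparator. Downstream panel assessments
    include per-gene ROC/AUC, two-cluster separation purity, tumor-stage
    trend screening, and Kaplan-Meier / log-rank survival splits. A seeded
    synthetic-cohort generator with planted effects, redundant duplicates,
    stage trends and expression-linked survival makes every stage testable
    without external cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    survival
Config/testthat/edition: 3
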