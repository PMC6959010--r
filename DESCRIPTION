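Package: cncl
Title: Stemness Signature Derivation, Scoring and Downstream Analysis for
    Two-Phenotype Breast Cancer Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a directional gene signature separating cancer-stem-cell-like
    and mesenchymal (CS/M) from non-stem-cell-like and epithelial (NS/E) samples
    from two independently labeled expression datasets, classifies samples by
    complete-linkage hierarchical clustering on the signature, computes a
    continuous stemness score as the difference of Pearson correlations to
    median phenotype centroids, traces phenotype plasticity across paired
    conditions, fits dose-response curves with a six-model logistic ensemble
    selected by residual standard error to obtain IC50 and activity-area
    summaries, screens drugs for phenotype-differential cytotoxicity, and
    evaluates prognostic value with a multiple-cutoff log-rank scan and
    multivariate Cox regression. Includes synthetic-data generators with
    planted ground truth for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
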