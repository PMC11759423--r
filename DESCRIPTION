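Package: clonalpred
Title: Genomic and Phenomic Prediction for Clonal Perennial Breeding Material
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation framework for genomic and phenomic prediction in
    clonally propagated perennial crops. Estimates clonal values and clonal
    mean heritability from multi-environment trials by REML, builds genomic
    (VanRaden) and phenomic (near-infrared spectra) relationship kernels,
    fits single- and two-kernel Bayesian ridge models by Gibbs sampling with
    a closed-form BLUP oracle, runs family-aware validation schemes
    (leave-one-family-out and repeated k-fold cross-validation), computes
    genotyping-dataset concordance metrics (non-reference discordance,
    dosage r-squared) and population-structure diagnostics (PCA, IBS k-NN
    networks, parallel analysis), all exercised end-to-end on a synthetic
    orchard generator with Mendelian family structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    igraph,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
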