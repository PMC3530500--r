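Package: ardi
Title: Average Risk Due to Interaction Tests for Gene-Gene Interaction
    Scans in Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide gene-gene (GxG) interaction searches in
    case-control genetic association studies. Implements the Average Risk
    Due to Interaction (ARDI) test, a one-degree-of-freedom interaction
    test with log-additive main effects and a single averaged interaction
    deviation, alongside multiplicative and unrestricted interaction
    models; covariate-adjusted per-study logistic fits; inverse-variance
    fixed-effect and DerSimonian-Laird random-effects meta-analysis with
    Cochran Q heterogeneity; two-stage screening (marginal association
    filter, greedy LD pruning, all-pairs interaction scan with Bonferroni
    accounting) and known-locus genome-wide scans; genomic-inflation
    diagnostics with a main-effect misspecification guard; two-locus
    interaction-pattern tables; and a multi-study case-control simulator
    with Hardy-Weinberg genotypes, linkage disequilibrium, configurable
    two-locus penetrance models, covariates, and imputation dosage noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
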