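Package: kinspan
Title: Kin-Cohort Survival GWAS of Parental Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of human lifespan
    under the kin-cohort design, in which subject genotypes are tested
    against parental survival. Implements the residualised Cox phenotype
    (Martingale residuals scaled by the proportion dead), common and
    sex-specific parent-trait combination, correlation-adjusted
    inverse-variance meta-analysis, effect-size scale conversions between
    hazard-ratio, longevity odds-ratio and years-of-life scales, Bayesian
    risk-factor-informed association (iGWAS) with permutation p-values,
    age- and sex-stratified hazard ratios with moderator meta-regression,
    disease-attribution statistics (lifespan variance explained, pruning,
    pleiotropy classification), and polygenic survival scores. A Gompertz
    cohort simulator with shared parental frailty provides fully synthetic
    data with the statistical structure the method assumes, so the entire
    pipeline is testable without access to any biobank.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
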