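Package: NeoVolNorm
Title: Normative Modelling of Neonatal Regional Brain Volumes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process normative modelling of regional neonatal brain
    volumes (absolute and relative) over sex, postmenstrual age at scan and
    age from birth in a preterm-to-term reference cohort, with individualized
    deviation z-scores for atypical cohorts and the downstream statistical
    battery: Mann-Whitney and Kruskal-Wallis tests, Cliff's delta effect
    sizes, Benjamini-Hochberg false discovery rate, Spearman correlation
    bands, LMS growth-chart z-scores, ordinary and quantile (median/quartile)
    regression of z-scores on age, extra sum-of-squares F-tests for slope and
    intercept differences, and whole-brain-volume covariation analysis.
    Includes a synthetic cohort generator so the full pipeline is testable
    without access to restricted neonatal imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StatisticalMethod, Regression, Normalization
RoxygenNote: 7.3.3
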