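Package: growthgwas
Title: Longitudinal Growth Modelling and Two-Stage GWAS of Early Growth Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models childhood body-mass-index trajectories with linear mixed
    models and Reed first-order growth curves, derives six early growth traits
    (peak height and weight velocity, age and BMI at the adiposity peak and at
    the adiposity rebound), and carries those traits through a two-stage
    genome-wide association workflow: per-study additive association with
    quality-control filtering, double genomic control, inverse-variance
    fixed-effects meta-analysis, follow-up selection, significance tiers, and
    downstream summary statistics (local false discovery rate, winner's-curse
    corrected effects, effective number of tests, summary-statistic genetic
    risk scores, conditional independence, and power).  A synthetic-cohort
    generator with known ground truth makes the full pipeline testable without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    vcfR,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
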