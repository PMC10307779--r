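Package: ethopain
Title: Ethogram Analysis of Thermal Pain Sensitivity and Opioid
    Reward-Related Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives formula-defined behavioral outcome measures (thermal
    hindpaw withdrawal reflex, locomotor habituation and sensitization,
    conditioned place preference and its extinction, chronic constriction
    injury effects) from tidy session-level records, runs the group-level
    statistical battery (one-sample, paired and pooled t tests,
    within-subjects ANOVA, Shapiro-Wilk, Pearson, Mann-Whitney), and
    performs the data-reduction pipeline: Pearson correlation matrix with
    angular-order-of-eigenvectors display ordering, 1-|r| distance,
    classical multidimensional scaling, and k-means clustering with a
    four-index vote for the cluster count.  Includes a synthetic-cohort
    generator with configurable latent trait correlation structure so
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
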