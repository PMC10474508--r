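Package: devsurv
Title: Developmental Surveillance Scoring and Trajectory Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies failures to attain age-normed developmental
    milestones with the Developmental Surveillance Score (DSS): each
    attempted milestone receives a discrete (DMAS) or linearized (LMAS)
    attainment score from the age-percentile brackets of an age-normed
    developmental scale, and scores are averaged over time windows and
    developmental domains. Per-domain score trajectories over seven age
    steps from birth to 36 months are clustered (k-means or Gaussian
    mixtures) into developmental patterns labelled adequate, catching-up,
    worsening or other. Includes rank-sum subgroup comparisons of the
    score against child and maternal characteristics, and a synthetic
    cohort generator emulating a maternal-child-health-clinic visit
    schedule with covariate-linked attainment probabilities and planted
    trajectory archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    tools,
    utils,
    mclust,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
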