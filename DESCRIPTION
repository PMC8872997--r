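Package: asymlink
Title: Polygenic Risk and Multivariate Brain Asymmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links polygenic risk scores to multivariate brain structural
    asymmetry. Provides construction and preprocessing of regional
    left-right asymmetry indexes (outlier removal, rank-based inverse
    normal transformation, covariate residualization), scalar-target
    canonical correlation analysis with per-region loadings, permutation
    nulls for comparing loading patterns between two risks and against
    sex-difference maps, logistic-regression contrasts of handedness
    groups, a type-driven phenome-wide association scan with
    false-discovery-rate control, and a synthetic cohort generator that
    emulates the statistical structure of large population imaging
    genetics datasets so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
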