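Package: bioagehf
Title: Biological-Age Clocks and Outcome Modelling for Heart Failure with
    Preserved Ejection Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction of clinical-biomarker biological-age clocks
    (Klemera-Doubal method age and Gompertz-mortality phenotypic age),
    biological-age-acceleration scores, and their downstream epidemiological
    analysis in cohorts of heart failure with preserved ejection fraction
    (HFpEF): echocardiographic derived indices (left-ventricular mass index,
    relative wall thickness, E/e'), HFpEF eligibility screening and the
    H2FPEF score, tiered Cox proportional-hazards and linear models,
    Kaplan-Meier/log-rank analysis by acceleration tertile, restricted cubic
    spline dose-response curves, and regression-based causal mediation of the
    acceleration-mortality association through cardiac structure and
    function. Includes a synthetic-cohort simulator with known latent aging,
    mediation structure and censoring, so that every stage of the pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
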