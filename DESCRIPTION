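Package: osteoburden
Title: Projecting Osteoporotic Fracture Burden and Disease-Management
    Interventions in Older Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-level, cross-sectional cohort model of the clinical
    and economic burden of osteoporotic fractures among women aged 70 years and
    older across eight European countries (2020-2040). Calibrates per-country,
    per-fracture-type annual risks to observed burden, applies hypothetical
    disease-management interventions (improved fracture-risk assessment,
    improved medication adherence, and their hierarchical combination) at
    configurable improvement fractions, and reports fracture counts, direct
    costs of care, per-100,000 rates and net benefits versus the status quo.
    Includes a synthetic-data generator with an individual-level
    microsimulation oracle for the cohort equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
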