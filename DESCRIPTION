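Package: bdmarkov
Title: Markov Cohort Cost-Utility Modelling for Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic Markov cohort model for cost-utility analysis
    of pharmacological and non-pharmacological interventions in bipolar
    disorder types I and II. Runs separate quarterly-cycle traces over the
    health states remission, depression, (hypo)mania and death for each
    subtype, values them in euros under a healthcare or societal perspective
    with discounting and half-cycle correction, and combines them into a
    prevalence-weighted incremental cost-effectiveness ratio. Includes the
    probability calculus used to derive cycle-level transition probabilities
    and intervention relative risks from published annual recurrence rates,
    age-dependent background mortality with state-specific mortality rate
    ratios, deterministic scenario analyses over the depression/mania time
    ratio, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
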