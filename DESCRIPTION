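Package: causalaf
Title: Causal Attribution Fractions for Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backdoor-adjusted population attribution fractions for disease
    incidence under a proportional-hazards model, estimated from conventional
    left-truncated, right-censored survival fits. Includes the confounder-weighted
    population fraction and its age-dependent form, the WHO-style comparison
    fraction, pairwise and effect-of-treatment-on-the-treated fractions,
    attributed case counts, a seeded simulator for confounded cohorts with rare
    Weibull-baseline event times (with interventional and counterfactual copies
    for ground truth), an independent causal oracle for validation, and a
    multi-disease landscape-survey pipeline with FDR selection, ranking tiers and
    chapter summaries.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble
Suggests:
    knitr,
    rmarkdown,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
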