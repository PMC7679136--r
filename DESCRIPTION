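Package: domstress
Title: Social Dominance Hierarchies and Sex-Specific Chronic Stress Outcomes in Group-Housed Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers social dominance hierarchies from dyadic chase-event logs
    using David's Scores, quantifies hierarchy structure (steepness, despotism,
    directional consistency, Landau's modified h'), tests rank stability
    against chance with exact binomial tests, and relates baseline dominance
    to post-stress behavioral and physiological outcomes through a
    rank-normalization, batch-adjustment and principal-component pipeline with
    sex-by-dominance interaction models. Includes synthetic-data generators
    (a Bradley-Terry-style latent-ability chase model and a structured outcome
    simulator) so the full analysis is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
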