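Package: awaresir
Title: Coupled Awareness-Epidemic Dynamics in Trusting and Distrusting Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an SIR epidemic coupled to contact-based spread of
    outbreak awareness in a population split into trusting individuals, who
    adopt better-quality information and take protective measures, and
    distrusting individuals, who adopt worse-quality information. Provides the
    full graded-awareness compartmental model, its aggregated form with an
    effective transmission rate, numerical phase-diagram scans that classify
    epidemic suppression versus mitigation, and the closed-form critical
    intervention-effectiveness curve in the fast-information limit, including
    the critical distrusting density beyond which suppression is impossible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
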