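Package: wcstlmm
Title: Latent Markov Modelling of Set-Shifting Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits covariate-stratified discrete-state latent Markov models to
    categorical Wisconsin Card Sorting Test (WCST) response sequences.
    Trial-level responses coded as correct (C), non-perseverative error (E)
    and perseverative error (PE) are partitioned into equal-sized task-phase
    windows; a latent first-order Markov chain with group-specific initial
    and transition probabilities and a shared multinomial measurement model
    is estimated by the EM algorithm with scaled forward-backward recursions.
    Includes BIC/AIC model selection across state counts and between basic
    and covariate models, post-fit dynamics (marginal state trajectories,
    absorbing-state detection, expected hitting times, seeded forecasting
    simulations), a synthetic-data generator for the full pipeline, and
    report/CLI helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
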