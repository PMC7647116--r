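Package: noisynewton
Title: Noisy-Newton Generative Models of a Visuomotor Puck-Sliding Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation and hierarchical Bayesian inference for a
    visuomotor puck-sliding task in the noisy-Newton tradition. Provides
    deterministic Newtonian mechanics (press-time law, frame-based sliding
    under friction, elastic collisions), a synthetic-cohort generator with
    log-normal (Weber-Fechner) perceptual and motor noise and three decision
    cost functions, MCMC inference of latent mass beliefs and variabilities
    from press-times, a collision observation model for inferring an unknown
    puck's mass, product-space Bayes factors for model selection, and
    distributional model checks (Kolmogorov-Smirnov, Kullback-Leibler,
    Bayesian change-point detection).
License: MIT
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
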