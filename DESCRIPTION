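Package: mimicryrisk
Title: Human-Induced Kill Risk of Batesian Mimic Snakes from Identification Surveys
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the extra risk a harmless viper-mimicking snake incurs
    from humans who are willing to kill venomous snakes. Fits intercept-only
    binomial GLMs for attitude proportions, a binomial generalized linear
    mixed model with crossed picture and respondent random intercepts
    (Laplace approximation) for species misidentification probabilities, and
    combines them into a kill-risk ratio with Monte Carlo uncertainty
    propagation. Includes a seeded synthetic survey generator for parameter
    recovery studies and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
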