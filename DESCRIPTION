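Package: twincomorbid
Title: Liability-Threshold Comorbidity Models for Twin Contingency Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Neale-Kendler family of thirteen comorbidity models
    (alternate forms, three independent disorders, random and extreme
    multiformity, correlated liabilities, direction-of-causation and chance)
    plus a saturated comparison model to collapsed twin-pair contingency
    tables of two binary lifetime diagnoses, by minimum chi-square or maximum
    likelihood on the 10-category by 2-zygosity multinomial. Includes a
    deterministic multivariate-normal band-probability engine specialised to
    exchangeable twin-pair liability covariances, descriptive comorbidity
    epidemiology including discordant-monozygotic-twin analysis and
    tetrachoric twin correlations, profile-likelihood confidence intervals,
    and a generative twin-pair simulator for every model mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
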