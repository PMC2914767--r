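Package: segkit
Title: Segregation Analysis of a Recessive Trait in Half-Sib Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood segregation analysis for binary (dominant/
    recessive) traits recorded as per-sire half-sib family counts, with
    ascertainment correction by truncate selection. Implements single-ratio
    estimation with profile-likelihood confidence limits, conditional
    estimation when the carrier frequency H is fixed, a two-ratio hard-max
    mixture fit with per-family assignment and likelihood-ratio comparison,
    G-square contingency heterogeneity tests, a Monte Carlo permutation test
    of segregation-ratio homogeneity, a two-linked-locus recessive model
    with maximum-likelihood estimation of the recombination fraction, and a
    seedable simulator of half-sib cross datasets for calibration studies.
    Ships the reciprocal Suri x Huacaya alpaca test-cross tables and the
    Suri x Suri half-sib series as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
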