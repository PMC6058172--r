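Package: srbsel
Title: Sex Ratio at Birth and Prenatal Sex-Selection Propensity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic models linking mean family size, son-preferring
    childbearing behaviour and the population sex ratio at birth (SRB).
    Family sizes are Poisson, birth sexes are Bernoulli, and sonless couples
    sex-select at a threshold birth order (universal-threshold model) or at
    their last birth (stopping-rule model). Provides closed-form forward
    predictions of the SRB and of the intervening-couple fraction, peak
    location over fertility, inversion of an observed (SRB, fertility) pair
    into a sex-selection propensity estimate, batch estimation from delimited
    tables, a seeded Monte Carlo cohort simulator that validates every closed
    form, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
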