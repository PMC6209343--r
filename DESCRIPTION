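Package: sharpnose
Title: Age, Growth and Maturity Analysis for Small Coastal Sharks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertebral band-pair ageing with seasonal partial ages,
    between-reader precision and bias statistics (average percent error,
    Chang's coefficient of variation, percent agreement, Bowker's test of
    symmetry), multi-model growth fitting (von Bertalanffy, logistic and
    Gompertz functions in three-parameter, fixed length-at-birth
    two-parameter, and zero-age-augmented forms) with AICc model selection
    and Akaike weights, Kimura's likelihood-ratio test for comparing growth
    curves between groups, and logistic maturity ogives (L50/L95, A50/A95)
    fitted by binomial GLM. Includes a synthetic specimen-table generator
    that emulates a seasonally reproducing, fast-growing coastal shark
    population so the complete pipeline can be exercised and validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
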