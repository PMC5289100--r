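Package: noisyletters
Title: Simulated Visual Acuity Testing with Luminance- and Contrast-Modulated Noise Letters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for synthesising luminance-modulated (first-order) and
    contrast-modulated (second-order) noise-letter optotypes, converting
    between letter size, viewing distance and logMAR acuity, running
    two-down/one-up four-alternative forced-choice adaptive staircases
    against simulated psychometric or template-matching observers, and
    analysing the resulting thresholds: group summaries, binocular
    summation ratios and mixed-design ANOVA. Includes a cohort simulator
    that emulates a two-group (older/younger) acuity study design and a
    fully seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
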