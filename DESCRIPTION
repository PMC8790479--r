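Package: nbscreen
Title: Expanded Newborn Screening by Tandem Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expanded newborn screening of inherited metabolic
    disorders (IMDs) from dried-blood-spot tandem mass spectrometry panels.
    Ships a 74-indicator amino acid / acylcarnitine marker panel with
    laboratory cut-off ranges and derived ratio markers, a configurable
    positive-rule classifier covering the screened disorders, a calibrated
    log-normal synthetic cohort generator, a two-tier screen / recall /
    confirm workflow simulator, incidence ("1:N") and category-proportion
    reporting, and HGVS variant allele-frequency tabulation for mutation
    spectrum summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
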