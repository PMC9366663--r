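Package: emfdose
Title: Occupational Exposure Assessment for Intermediate-Frequency and
    Pulsed Electromagnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of combined occupational exposure to
    intermediate-frequency electromagnetic fields from electromagnetic
    article-surveillance (EAS) gates and pulsed magnetic fields from book
    check units (BCUs), as encountered by library workers. Implements the
    ICNIRP 2010 occupational reference levels and basic restrictions,
    a power-law distance-decay model for gate fields, pulse waveform
    characterization (peak, FWHM, peak dB/dt), short-term exposure ratios
    (E1-E3), questionnaire-driven weekly dose indices (D1-D3),
    exposure-pattern classification, cohort summaries, and a synthetic
    questionnaire-cohort generator for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
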