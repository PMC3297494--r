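Package: ratioquant
Title: Ratiometric Two-Channel Immunofluorescence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-quantitative quantification of protein expression from
    dual-channel immunofluorescence micrographs: per-cell ratios of mean
    target-channel (green, FITC) to mean housekeeping-channel (red, Texas
    Red) pixel intensity, fixed-size per-sample cell collections, sample
    mean-ratio summaries, and group-level hypothesis tests (pooled and
    Welch t-tests, one-way ANOVA, chi-square and Fisher's exact tests on
    clinical contingency tables). Includes a seeded synthetic micrograph
    generator with per-cell ground truth for end-to-end validation, plus
    null-rejection and power simulations for the testing layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
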