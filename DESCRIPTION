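Package: blindscore
Title: Blinded, Randomized Multi-Observer Image Scoring and Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-hostable workflow for collaborative, blinded image
    analysis by multiple observers. Projects bundle questions, data groups
    and anonymized images; observers work through a randomized, forward-only
    sequence behind a non-guessable share token, answering single-choice or
    numeric questions and taking calibrated geometric measurements (count,
    length, angle, freehand area, pixel probe) with DICOM pixel-spacing or
    known-object calibration. Responses are merged server-side into combined
    and per-observer/per-group summaries with CSV export, plus Spearman and
    exact Mann-Whitney statistics for method-comparison studies. Includes a
    synthetic-image and simulated-observer generator with known ground truth,
    and an HTTP layer exposing the full master and observer workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    openssl,
    png,
    jpeg,
    zip,
    httpuv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    httr,
    withr
Config/testthat/edition: 3
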