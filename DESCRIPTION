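Package: promstrength
Title: Sequence-Based Prediction of Core Promoter Strength in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the strength of Saccharomyces cerevisiae promoters from
    the 60 bp core-promoter window spanning positions -49..+10 relative to the
    transcription start site. Builds position frequency, probability and
    log-odds scoring matrices from an aligned promoter population, scores
    whole windows and sub-segments, fits the linear model relating normalized
    segment scores to fluorescence-derived promoter strengths with full
    ordinary-least-squares diagnostics, scans segment endpoints to locate the
    minimal predictive region, pools model parameters across fluorescence
    channels by inverse-variance weighting, and classifies query promoters as
    weak, moderate or strong. Includes a seeded synthetic-data generator with
    known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
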