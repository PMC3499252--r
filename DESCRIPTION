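Package: wormmate
Title: Quantification of C. elegans Male Mating Behavior and Dual-Reporter
    Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to score Caenorhabditis elegans male mating behavior and
    dual-reporter (G-CaMP/mDsRed) calcium imaging recordings. Provides ROI
    mean-pixel-intensity extraction from two-channel time-lapse stacks,
    red-channel-referenced photobleaching and motion-artifact correction with
    percent dF/F0 computation and calcium-event classification, spicule-thrust
    rhythmicity detection from intensity-variability traces, the spicule
    insertion efficiency score (E_SI) with posture and locomotion metrics, and
    the categorical/nonparametric statistics used for group comparisons. A
    synthetic-data generator produces image stacks, behavioral timelines and
    oscillatory thrust traces with known ground truth so the full analysis
    chain is testable without microscopy recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
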