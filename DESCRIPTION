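Package: mycomorph
Title: Single-Cell Morphometry of Polar Growth in Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies asymmetric polar elongation in rod-shaped bacteria
    (mycobacteria) from multi-channel fluorescence microscopy. Extracts
    length-normalized axial intensity profiles along the medial axis of each
    cell, detects fluorescent D-amino acid (HADA) incorporation foci and
    pole/septum landmarks with prominence-calibrated peak detection, fits
    polar intensity decay slopes, classifies old versus new poles, and
    performs spectral phasor analysis of hyperspectral (LAURDAN) stacks,
    including two-reference linear-combination fractions. Ships a seeded
    synthetic-image generator with full ground truth that emulates control,
    deletion and overexpression phenotypes, so the whole pipeline is testable
    end to end, plus population statistics and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
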