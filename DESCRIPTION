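Package: syrinxlab
Title: Analysis Pipeline for Syringeal Muscle Physiology, Morphometry, Song
    Acoustics, Proteomics and Song Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify vocal (syringeal) muscle performance and its
    behavioural consequences in songbirds. Computes twitch contraction speed
    (full width at half maximum) and maximal isometric stress from in vitro
    force recordings; segments laminin-stained muscle cross-sections with an
    H-minima watershed and classifies myofibres as superfast or fast from
    MY-32 staining intensity; extracts calibrated acoustic features from song
    recordings (source level, Wiener entropy, Yin fundamental frequency),
    detects and aligns motifs, segments syllables and compares pre/post
    conditions; quantifies label-free proteomics via top-3 peptide peak areas
    with total-sum and Histone H4 normalization and paired differential
    abundance; and analyses operant keypeck logs with a Williams-corrected
    G-test of stimulus preference. Seeded synthetic-data generators with
    persisted ground truth make every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    tiff,
    png
Config/testthat/edition: 3
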