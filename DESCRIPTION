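Package: netrack
Title: Nuclear Envelope Aggregate Tracking and Meiotic Cytology Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of chromosome-end (SUN-1)
    aggregate mobility on the nuclear envelope of C. elegans meiotic nuclei,
    together with the cytological statistics used in germline studies. Provides
    a seeded synthetic time-lapse generator with ground-truth tracks (sphere-
    constrained run-and-pause motion, Gaussian optics, Poisson noise,
    photobleaching, aggregate fusion and splitting), an image-preparation chain
    (maximum-intensity projection, background subtraction, subpixel drift
    registration), multiscale spot detection with focus/patch classification,
    optimal-assignment track linking with fusion/split annotation, projected-
    speed and arc-coverage kinematics, and zone-based cytology statistics
    (pairing with Fisher's exact test, diakinesis DAPI-body/bivalent
    accounting with exact Mann-Whitney comparisons, focus-count histograms,
    synapsis-association classification, per-worm respiration normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
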