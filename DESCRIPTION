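Package: pennate
Title: Clustering-Based Pennation Angle Estimation from B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the pennation angle of pennate skeletal muscle from
    B-mode ultrasound frame sequences by an unsupervised clustering pipeline:
    brightness thresholding of fascicle and aponeurosis regions of interest,
    density-based pixel clustering (DBSCAN, with K-means and single-linkage
    agglomerative alternatives), tubular re-clustering of collinear fragments
    via corner-point orientation and connection angles, value-based selection
    of the target fascicle and aponeurosis, optional elliptical brightness
    augmentation, and temporal smoothing with a skew-Gaussian viscosity weight
    that rejects outlier frames. Includes a synthetic B-mode scene generator
    with known ground-truth geometry for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
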