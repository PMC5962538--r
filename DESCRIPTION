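Package: conefinder
Title: Cone Photoreceptor Localisation in AOSLO Split-Detection Images with
    Multidimensional LSTM Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semantic segmentation of adaptive optics scanning light
    ophthalmoscope (AOSLO) split-detection retinal images and automatic
    localisation of cone photoreceptor centroids. Implements two-dimensional
    multidimensional long short-term memory (MDLSTM) layers with a bounded
    cell state and an anti-diagonal wavefront scan, a compact
    convolution/MDLSTM segmentation network trained with the Generalised
    Dice Loss under an RMSProp/early-stopping regime, adaptive local-maxima
    centroid recovery with validation-set calibration, and a point-matching
    evaluation protocol (Dice coefficient and Bland-Altman agreement
    statistics). A synthetic split-detection mosaic generator with exact
    ground-truth centroids supports end-to-end testing in dense (healthy)
    and sparse (diseased) photoreceptor regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    png,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
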