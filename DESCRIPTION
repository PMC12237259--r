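Package: nmjquant
Title: Quantitative Analysis of Drosophila NMJ Presynapses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of the quantitative analysis stack
    used in Drosophila larval neuromuscular junction (NMJ) presynapse
    studies: confocal synaptic-punctum segmentation and density metrics
    inside an HRP-derived neuronal mask, Pearson colocalization with a
    Costes auto-threshold and a flipped-channel negative control,
    STED-scale active-zone-centered nearest-neighbor distance and radial
    intensity profile analyses, electrophysiological trace metrics
    (template-matched miniature event detection, evoked kinetics, quantal
    content, paired-pulse ratios, and readily-releasable-pool
    back-extrapolation from 100-Hz trains), and behavioral indices from
    T-maze counts with the accompanying statistical decision tree. All
    stages are exercised end-to-end on synthetic data with known ground
    truth generated by the package itself.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
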