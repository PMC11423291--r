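Package: avalanchr
Title: Neuronal Avalanche Criticality in Up and Down States of Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neuronal-avalanche statistics in bistable
    (up/down alternating) spike recordings from dissociated neuronal cultures.
    Provides spike-raster containers and delimited-file I/O, population-rate
    smoothing and Schmitt-trigger segmentation into up and down states,
    per-state avalanche detection over grids of time-bin widths with patch
    subsampling, finite-size scaling collapse across bin widths for power-law
    and exponential-like avalanche distributions, Kolmogorov-Smirnov power-law
    goodness of fit with an extended-range search, and a spatially embedded
    quadratic integrate-and-fire network simulator with short-term synaptic
    depression that generates synthetic culture recordings with up/down
    alternation. A critical branching-process generator is included as a
    mean-field reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
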