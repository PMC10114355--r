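Package: aggremorph
Title: Morphometry and Kinetics of Amyloid-Like Protein Aggregates
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of fluorescence and electron micrographs of
    amyloid-like protein aggregates. Provides chromatic-aberration channel
    registration and rolling-ball background subtraction, thresholded
    connected-component detection of aggregates, skeleton-graph shape
    descriptors (longest chain, branch points, mean width, punctum counts by
    Laplacian-of-Gaussian blob detection), PCA plus k-means morphological
    classification into linear-fractal, branched-fractal and fibril classes,
    sigmoid fitting of thioflavin-T aggregation kinetics with tangent-intercept
    lag times, and fibril width profiling from negative-stain TEM images. A
    synthetic-scene simulator (random-walk punctum-docking growth model,
    worm-like-chain fibrils, Poisson-Gaussian camera noise, sigmoidal kinetics,
    edge-contrast TEM ribbons) makes every stage testable with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    igraph,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), knitr, optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
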