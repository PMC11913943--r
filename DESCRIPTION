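Package: encroachr
Title: Land-Cover Change, Intensity Analysis and CA-Markov Simulation of
    Bush Encroachment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing woody-plant encroachment into grasslands
    from categorical land-cover maps: cross-tabulation of map pairs into
    transition matrices, completion of partially known matrices from their
    marginals, three-level Intensity Analysis (interval, category,
    transition) with active/dormant and targeting/avoiding classification,
    map-accuracy decomposition (overall/producer's/user's accuracy, Cohen's
    kappa, quantity and allocation disagreement, QADI index), and CA-Markov
    projection of future land cover driven by a multilayer-perceptron
    transition-potential model over terrain covariates (slope, aspect,
    topographic wetness index, distance to roads). Includes a seeded
    synthetic-landscape generator with known logistic transition dynamics
    so the full pipeline is testable without satellite imagery, and light
    raster I/O (single-band GeoTIFF and ESRI ASCII grids).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
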