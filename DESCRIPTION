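Package: uavchl
Title: Chlorophyll Estimation from UAV RGB Imagery with Vegetation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating maize canopy chlorophyll (SPAD scale)
    from low-altitude RGB imagery. Computes a registry of 18 RGB vegetation
    indices on band-normalized chromatic coordinates or HSV channels, segments
    green vegetation from soil background with the excess-green minus
    excess-red (ExG-ExR) rule, aggregates per-plot index features over regions
    of interest, quantifies how flight altitude (ground sampling distance)
    degrades index-chlorophyll regressions, and fits backpropagation neural
    network, support vector and random forest regressors for per-pixel
    chlorophyll mapping. Includes a synthetic field-scene generator so the
    whole analysis is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    jsonlite,
    png,
    tiff,
    nnet,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
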