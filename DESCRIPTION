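Package: barogeo
Title: Geometric Characterization of Baroreflex-Mediated Cardiorespiratory
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts electrocardiogram, continuous blood-pressure and
    respiratory-flow recordings into beat-to-beat interval (BBI), systolic
    and diastolic pressure (SBP, DBP) and respiratory-cycle (TT) event
    series, partitions their beat-scale variability by the direction of
    vascular change (up, no-change, down sub-spaces), characterizes the
    cardiorespiratory scatterplot of each sub-space with a 95%-containment
    polygon (shoelace area, centroid, triangle-fan morphology) and
    descriptive statistics, and screens the resulting index set with
    Mann-Whitney tests before classifying subject groups with kernel
    support vector machines under leave-one-out cross-validation.  A
    coupled cardiorespiratory-vascular signal simulator with known ground
    truth supports testing and power analysis without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
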