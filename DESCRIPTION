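Package: podcompare
Title: Co-Deployment Comparison of Echolocation Click Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing co-deployed echolocation click loggers
    (C-POD / F-POD style detectors) monitoring harbor porpoise. Simulates
    two-detector click-train datasets with known ground truth, aggregates
    detections into detection-positive minute/hour/day metrics under train
    quality filters, classifies foraging buzzes from inter-click intervals
    with a Gaussian mixture on the log scale, computes inter-detector
    comparison statistics (Kendall rank correlation, detection ratios,
    matched-bin proportions), and fits negative-binomial additive models of
    hourly occurrence and foraging rate with cyclic smooths and AR(1)
    residual structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
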