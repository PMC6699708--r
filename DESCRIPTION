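Package: melonpheno
Title: Non-Destructive Fruit Quality Monitoring from External Phenotype Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-based pipeline for predicting internal quality traits of
    netted muskmelon (Cucumis melo) from external phenotype. Segments the
    fruit from a blue backdrop with an excess-blue (2B-R-G) colour index and
    Otsu thresholding, extracts 65 external parameters (45 colour statistics
    over RGB/CIELAB/HSV, 6 gray-level co-occurrence texture statistics of the
    surface netting, 14 contour morphology descriptors), screens them against
    internal phenotypes by Pearson correlation (P < 0.05), and fits random
    forest regression models per trait with mtry tuning, repeated 10-fold
    cross-validation, permutation importance and a top-10 simplified model.
    Includes a seeded synthetic scene and phenotype generator so the whole
    pipeline is testable without any raw image deposit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
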