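Package: ductmorph
Title: Morphometric Features for Grading Pancreatic Duct Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation and morphometric feature extraction for single-duct
    H&E histology images of pancreatic tissue, aimed at detecting ductal
    adenocarcinoma and separating its well- and moderately-differentiated
    grades. Segments the duct lumen (maximum-entropy thresholding, direction
    cumulative map seeding, seeded region growing) and the nuclei (k-means
    colour clustering, watershed), partitions nuclei into epithelial and
    non-epithelial sets, and computes twelve classical morphometrics plus
    duct-atypia features: the area-preserving ideal lumen boundary, the
    signed atypia-amplitude signature, RMSAA, the total sum of atypia
    volatilities at perceptually important points, atypia-region counts and
    ratios, and cytoplasm-length statistics. Includes a synthetic duct
    phantom generator with analytic ground truth, and an SVM bootstrap
    evaluation protocol with grid search, confusion metrics, ROC/AUC and
    ANOVA/LSD feature screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    mgcv,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
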