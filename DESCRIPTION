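Package: gaitTDA
Title: Topological Analysis of Gait Stride-Interval Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies neuro-degenerative gait from stride-interval time
    series using topological data analysis. Stride series are cleaned
    (startup removal, median replacement of turn-around outliers),
    delay-embedded into two-dimensional point clouds, reduced to landmark
    sets by maxmin subsampling, and summarised by the persistent homology
    of the Vietoris-Rips filtration. H1 persistence diagrams are converted
    to persistence-landscape feature vectors and evaluated with
    leave-one-out cross-validated classifiers (Gaussian naive Bayes,
    decision tree, random forest, k-nearest neighbours), reporting
    confusion matrices, accuracy, sensitivity, specificity and AUC.
    Includes Wasserstein and bottleneck diagram distances and a synthetic
    cohort generator emulating stride-interval recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    e1071,
    rpart,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
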