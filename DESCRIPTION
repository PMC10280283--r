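Package: phca
Title: Persistent Homology Classification of Labeled Point Clouds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Supervised classification of points in Euclidean space by the
    change they induce in the persistent homology of each class point cloud.
    Provides the Vietoris-Rips filtration, persistence computation via
    boundary-matrix reduction over the two-element field with a union-find
    fast path for connected components, bottleneck and Wasserstein distances
    between persistence diagrams, the total-persistence score classifier,
    stratified k-fold cross-validation with per-class performance metrics,
    the Nemenyi post-hoc comparison of classifiers, and generators for
    synthetic point clouds sampled uniformly from a circle, a sphere and a
    torus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    optparse,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
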