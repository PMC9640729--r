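Package: bindresp
Title: Binding-Site Geometry Features and Multiclass Drug-Response Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts geometric descriptors of protein-ligand binding from
    multi-model PDB trajectory snapshots: alpha-shape surface atoms of a
    weighted point set, solid-angle convexity scores, drug-target interface
    sets, convex/concave matching rates, distance-threshold connectivity,
    binding-site positioning distances, and geometric hydrogen-bond counts.
    Combines these with encoded clinical covariates and MM-GBSA energy
    components into a normalized feature table, and trains four-class
    drug-response classifiers under a nested cross-validation protocol with
    grid search, y-scrambling, feature-group ablation, and stratified
    evaluation. Includes synthetic-fixture generators (toy weighted
    complexes, jittered trajectories, labeled cohorts) so the full pipeline
    is testable without private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    xgboost,
    e1071,
    class,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
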