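Package: mhra
Title: Multilevel Heterogeneous Recurrence Analysis for Multichannel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing the nonlinear, nonstationary dynamics of
    multichannel physiological recordings (such as multi-lead EEG) through
    multilevel heterogeneous recurrence analysis. Signals are embedded into a
    low-dimensional state space, symbolized by a Voronoi tessellation of the
    state space, encoded as a chaos-game (iterated function system) fractal,
    and quantified with heterogeneous recurrence metrics at several transition
    levels. The resulting feature vectors feed a one-vs-all ensemble
    classification pipeline with LASSO stability selection, repeated-split
    evaluation, and sensitivity analysis. Includes synthetic generators
    (Lorenz and Roessler attractors, labeled surrogate multichannel signals)
    so the full pipeline can be exercised without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    glmnet,
    randomForest,
    xgboost,
    rpart,
    vegan,
    deSolve,
    pROC,
    uwot,
    Rtsne,
    RSpectra,
    FNN
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
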