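Package: tsignn
Title: Temporal-Setting Missing-Data Imputation with Joint Bipartite Graph Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing values in multivariate time series by
    representing the sliding-window-flattened data matrix as a joint bipartite
    graph (observation nodes, feature nodes, observed values as attributed
    edges) and training a GraphSAGE-style graph neural network with edge
    embeddings to predict every cell. Includes sequence-length selection for
    irregularly sampled multi-entity data, a model-size estimator and budget
    gate, MCAR masking and RMSE evaluation on masked cells, downstream
    congeniality assessment (R-squared of gradient-boosted and linear models on
    imputed versus original data), classic baselines (mean, interpolation,
    k-nearest neighbours), and a synthetic generator for autocorrelated,
    cross-correlated series with known label structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    xgboost,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
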