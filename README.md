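# tsignn

Missing-data imputation for multivariate time series via **joint bipartite
graph neural networks**, with the full masking/RMSE/congeniality evaluation
protocol and a synthetic-data generator.

## The problem and the model

Repeated measurements — daily stock prices, sub-hourly energy meters, ICU
labs and vitals — are correlated both across time and across features, and
they are routinely incomplete. A bipartite-graph imputer represents the
`T x F` data matrix as a graph with one *observation node* per row, one
*feature node* per column and one attributed edge per observed cell, then
trains a message-passing network to predict edge values; but the plain
bipartite construction treats rows as independent, discarding temporal
structure.

`tsignn` implements the temporal extension: the series is cut by a stride-1
sliding window of length `L` into a `(T-L, L, F)` array and reshaped to a
`((T-L)·L, F)` design matrix whose rows become the observation nodes. The
window layout encodes sequence information in the node set itself — no
observation–observation edges are ever created, so the graph stays bipartite.
A GraphSAGE-style GNN with edge embeddings (3 layers, 64 hidden units, mean
aggregation, ReLU; Adam, learning rate 0.001; per-epoch edge dropout 0.3) is
trained with MSE on the observed edges and predicts every cell; the up-to-`L`
imputed copies of each source cell are reconciled by their mean. The number
of trainable edges of a complete input is

    size = (T − L) · L · F   (kept ≤ a budget, default 4,000,000)

and `estimate_size()`/`tsi_gnn()` gate training on it. For irregular
multi-entity data the sequence length is the rounded mean entity length
(entities shorter than 9 excluded) and doubles as a per-entity cap.

The evaluation harness hides 30% or 60% of a complete dataset completely at
random, scales features to `[0, 1]`, and scores (i) RMSE on the masked cells
on the normalized scale and (ii) *congeniality*: R² of gradient-boosted trees
and linear regression predicting a label on imputed vs original data under a
shared 70:30 holdout — a near-zero gap means imputation preserved the
feature–label structure. Classic baselines (mean, linear/spline/cubic
interpolation, distance-weighted kNN) are included.

## Worked example

```r
library(tsignn)

spec <- synth_spec(n_timesteps = 200, n_features = 4, ar = 0.8, seed = 42)
ts <- generate_regular(spec)                      # complete AR(1)-factor series
masked <- apply_mcar_mask(ts, rate = 0.3, seed = 7, label_protected = FALSE)
masked$masked
#> <temporal_series> 200 timesteps x 4 features, 236 missing cells (29.5%)

fit <- tsi_gnn(masked$masked, sequence_length = 10,
               config = imputer_config(epochs = 300, seed = 1))
fit
#> Temporal-setting graph imputation model
#>   representation: joint bipartite graph, sequence length 10
#>   graph: 1900 observation nodes, 4 feature nodes, 5341 observed edges
#>   size: 7,600 (threshold 4,000,000)
#>   training: 300 epochs, final MSE 0.00516

truth <- normalize_series(ts, stats = fit$norm_stats)$series
rmse_masked(imputed_series(fit, "scaled"), truth, masked$mask)
#> [1] 0.1109
rmse_masked(baseline_impute(normalize_series(masked$masked)$series, "mean"),
            truth, masked$mask)
#> [1] 0.2053
```

The windowed graph imputer roughly halves the mean-imputation error on this
autocorrelated fixture. `fitted(fit)` returns the completed matrix on the
original scale (observed cells passed through untouched), `plot(fit)` shows
the training-loss trace, and `predict(fit, newdata)` imputes new data with
the trained parameters — the model is inductive, no retraining needed.

## Command line

A thin CLI wraps the same functions:

```sh
exec/tsignn size --obs 4120 --seq-len 21 --features 6      # prints: size 516474 threshold 4000000 ok
exec/tsignn simulate --spec spec.yaml --out data/
exec/tsignn impute --input data.csv --out imputed.csv --seq-len auto
exec/tsignn evaluate --input data.csv --out-dir results/ --methods mean,tsignn
```

Every run writes a JSON manifest (config, seed, input hash) sufficient to
reproduce it; `evaluate` reruns are byte-identical.

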