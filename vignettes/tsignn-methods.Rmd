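---
title: "Temporal-setting imputation with joint bipartite graphs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-setting imputation with joint bipartite graphs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multivariate time series in finance, energy metering and intensive-care
monitoring are routinely incomplete. Two kinds of structure make imputation
tractable: adjacent observations are correlated in time, and features are
correlated with one another. Classic imputers exploit one axis or the other —
interpolation uses time but ignores cross-feature structure, matrix-completion
and k-nearest-neighbour methods use cross-feature structure but treat rows as
exchangeable. `tsignn` implements a graph-based imputer that uses both.

## The joint bipartite graph

A static bipartite-graph imputer represents a data matrix as a graph with one
*observation node* per row, one *feature node* per column, and one attributed
edge per observed cell carrying its value. A graph neural network trained to
predict edge values from message passing then imputes the missing cells. The
bipartite construction implicitly assumes rows are independent — false for
repeated measurements.

The joint bipartite construction keeps the bipartite property (no
observation–observation edges are ever created) but encodes temporal order in
the observation-node set itself. The `T x F` series is cut by a stride-1
sliding window of length `L` into a `(T-L) x L x F` array, which is reshaped
row-major over (window, step) into a `(T-L)*L x F` design matrix. Each flat
row becomes an observation node, so every source row appears in up to `L`
nodes and the window layout carries sequence information into message passing
without explicit temporal edges. The reshape is exactly invertible, which the
package asserts bit-exactly (`flatten_windows()` / `restore_windows()`).

Two conventions deserve note:

* **Window count is `T - L`, not `T - L + 1`.** The construction drops one
  admissible window; with starts `0 .. T-L-1` the final source row is covered
  by no window. `collapse_to_series()` therefore raises on truly uncovered
  rows by default; the fitting pipeline passes the source value through for
  that row and fills any still-missing cell there from the nearest covered
  timestep of the same feature. At `T = 300, L = 10` this affects at most one
  row in 300.
* **Cell reconciliation.** After imputation each source cell has up to `L`
  imputed copies; `tsi_gnn(reducer=)` reconciles them, by unweighted mean by
  default (an unbiased combination under exchangeable window errors; `first`
  and `median` are provided).

The graph size — the number of trainable edges on a fully observed input —
is `(T - L) * L * F`. `estimate_size()` computes it and `tsi_gnn()` refuses
to train past a budget (default four million, a practical laptop-scale limit)
unless forced. Masking removes edges, so higher missing rates give smaller
graphs.

## The network

The architecture is a GraphSAGE-style message-passing network with edge
embeddings. Feature node `f` is initialized to the F-dimensional one-hot of
`f`; observation nodes to the all-ones vector of dimension F; the initial
edge state is the scalar scaled value. Per layer, for the message from
neighbour `j` to node `i` along edge with state `e`:

```
m_ij = ReLU(W [h_j, e_ij] + b_m)        message (edges used in both directions)
a_i  = mean over incoming m_ij          aggregation (0 for isolated nodes)
h_i' = ReLU(Q [h_i, a_i] + b_q)         node update
e'   = ReLU(P [e, h_u', h_v'] + b_p)    edge-embedding update
```

After three layers (64 hidden units), a one-hidden-layer ReLU head maps
`[h_u, h_v]` to the predicted value of cell `(u, v)`. Training minimizes mean
squared error over the observed edges only, full batch, with Adam at learning
rate 0.001; a fresh edge-dropout draw each epoch (rate 0.3) removes a fraction
of observed edges from message passing while they remain prediction targets,
which regularizes exactly the train-time/impute-time mismatch the model faces
on missing cells. Defaults (3 layers, 64 units, mean aggregation, ReLU, 2000
epochs, lr 0.001) follow the reference setup this architecture inherits from;
the desk-scale studies in the tests and acceptance script use 500 epochs,
which suffices at their graph sizes. The aggregator is a pluggable interface
with only `mean` shipped; order-sensitive aggregators (e.g. LSTM) are
deliberately out of scope.

The forward and backward passes are implemented in base R with `Matrix`
sparse incidence operators. Node-side linear maps are applied to the
node-embedding matrix first and gathered per edge afterwards, and gradients
are scatter-added back to node space before the dense transforms, so the
dense GEMMs stay node-sized. The analytic gradients are verified against
central finite differences in the test suite (agreement to ~1e-8 relative).

Because the network is inductive — parameters do not depend on node
identity — a model trained on one graph imputes any graph with the same
feature schema: `predict(fit, newdata)` windows and scales `newdata` with the
stored statistics and predicts without retraining.

### Numerical choices

* Glorot-uniform initialization, zero biases; one master seed derives
  independent init, dropout and mask streams, so fits are bit-reproducible.
* Observed cells are passed through unchanged on output (imputation
  contract); this is invisible to masked-cell RMSE but matters downstream.
* A non-finite training loss aborts with a diagnostic; optional global
  gradient-norm clipping (`grad_clip`) is off by default.
* Constant features scale to 0 under min–max scaling, with a warning.

## Irregular multi-entity data

For collections with per-entity lengths (the ICU-style case),
`determine_sequence_length()` excludes entities shorter than a minimum
(default 9), then uses the rounded mean length (rounding half away from zero)
as both the window length and the per-entity cap — the max-sequence-length
convention of EHR pipelines. Entities longer than the cap are truncated to
their most recent `L + 1` rows (one window); entities with `T <= L`
contribute a single window front-padded with missing rows, and padded cells
generate no edges. Cells that end up outside every window keep their observed
values; missing ones are filled from the nearest covered timestep.

## Evaluation protocol

The evaluation harness recreates a missing-completely-at-random scenario on
complete data: each maskable cell is hidden independently with probability
0.3 or 0.6 *before* windowing (so all window copies of a cell share their
missingness), data are scaled per feature to [0, 1] by statistics computed on
observed cells (z-scoring available), imputation happens on the scaled data,
and masked-cell RMSE is computed on that scale without rescaling model
output. Downstream *congeniality* asks whether imputation preserved
feature–label structure: a gradient-boosted regression-tree model and an
ordinary least-squares model are fit to `label ~ features` on the first 70%
of rows and scored by R² on the last 30%, identically for original and
imputed data; the gap (imputed minus original) is zero for perfect imputation,
which the tests assert as the protocol's fixed point. The 70:30 split is
time-ordered by default to avoid leakage between adjacent windowed rows
(random split by flag); the label column is protected from masking by default
so R² measures feature-imputation quality. Binary labels reuse the same R²
machinery rather than switching to classification metrics, keeping one scale
across continuous and categorical labels.

Baselines: per-feature observed mean; linear, natural-spline and cubic
interpolation along time with nearest-observed boundary fill; and
distance-weighted k-nearest-neighbour rows (Euclidean distance on jointly
observed features, weights 1/d, neighbours restricted to rows observing the
target feature).

## The synthetic generator

Real datasets are deliberately not required. `synth_spec()` defines a
k-factor model: latent AR(1) processes `x_t = phi x_{t-1} + eps_t`
(stationary start, unit innovation variance) mapped through an `F x k`
loading matrix plus Gaussian observation noise, with an optional label that
is a stated linear combination of features (or its thresholded binary
version). This is the simplest generator exhibiting both correlation axes the
imputer is supposed to exploit; tests verify the realized lag-1
autocorrelation, the loading-implied covariance, and that temporal signal is
genuinely present (interpolation beats mean imputation at high `phi`).

What it does not emulate: heavy tails, regime switches, seasonality,
non-stationary trends, informative missingness. Passing tests on this
generator show the mechanics work and that the windowed representation helps
when autocorrelation exists; they do not certify performance on any real
dataset or under non-MCAR mechanisms (out of scope throughout).

Default study conditions, chosen once: regular fixture `T = 300, F = 5,
L = 10, phi = 0.8, noise_sd = 0.1` (graph size 14,500 — far under budget,
trains in minutes on one CPU); irregular fixture 550 entities with lengths
uniform on {9..21} (mean 15, matching the sequence length the selection rule
should return); masking rates 0.3 and 0.6; 500 epochs for the desk-scale
studies; medians over 3 seeds for stochastic comparisons.

## Known limitations

* The window count convention loses one window and leaves the final row
  uncovered; the carry-forward fill for that row is a pragmatic repair.
* Full-batch training bounds the practical graph size; the budget gate makes
  the bound explicit rather than removing it.
* Only the mean aggregator and MCAR masking are implemented; MAR/MNAR
  mechanisms, multiple-imputation pooling and discrete-edge heads are
  non-goals.
* RMSE over a mixed continuous/categorical schema treats the binary feature
  as {0,1}-valued continuous, a known bias of single-metric evaluation.
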