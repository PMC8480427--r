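#' Configuration of the graph-neural-network imputer
#'
#' Defaults follow the reference setup: a 3-layer GNN with 64 hidden units,
#' mean aggregation, ReLU activation, Adam at learning rate 0.001, 2000
#' epochs, full-batch training on the whole graph, and per-epoch edge dropout
#' at rate 0.3 (dropped edges leave message passing for that epoch but remain
#' prediction targets).
#'
#' @param n_layers number of message-passing layers.
#' @param hidden_dim width of node/edge embeddings and the prediction head.
#' @param epochs training epochs (full-batch).
#' @param learning_rate Adam step size.
#' @param edge_dropout per-epoch edge dropout probability in `[0, 1)`.
#' @param aggregation neighbourhood aggregator; only `"mean"` is shipped (the
#'   interface is pluggable; order-sensitive aggregators such as LSTM are out
#'   of scope).
#' @param activation `"relu"` (the only shipped activation).
#' @param grad_clip global gradient-norm cap; `Inf` disables clipping.
#' @param seed master seed; initialization and dropout streams are derived
#'   from it.
#' @return an object of class `imputer_config`.
#' @export
imputer_config <- function(n_layers = 3, hidden_dim = 64, epochs = 2000,
                           learning_rate = 0.001, edge_dropout = 0.3,
                           aggregation = "mean", activation = "relu",
                           grad_clip = Inf, seed = 1) {
  stopifnot(n_layers >= 1, hidden_dim >= 1, epochs >= 1, learning_rate > 0,
            edge_dropout >= 0, edge_dropout < 1)
  aggregation <- match.arg(aggregation, "mean")
  activation <- match.arg(activation, "relu")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 edge_dropout = edge_dropout, aggregation = aggregation,
                 activation = activation, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "imputer_config")
}

# ---- internal tensor form of a bipartite_graph -------------------------------
# obs nodes 1..m, feature nodes m+1..m+n. X0: initial node features
# (ones for observation nodes, one-hot for feature nodes). E0: 1-dim edge
# input = the scaled observed value. Su/Sv: fixed K x N incidence matrices of
# the undirected edge endpoints, used for scatter-adds in backprop.
graph_tensors <- function(graph) {
  m <- graph$n_obs; n <- graph$n_feat; N <- m + n
  K <- nrow(graph$edges)
  uo <- graph$edges$obs
  vf <- m + graph$edges$feat
  X0 <- rbind(matrix(1, m, n), diag(n))
  E0 <- matrix(graph$edges$value, K, 1)
  list(m = m, n = n, N = N, K = K, uo = uo, vf = vf,
       y = graph$edges$value, X0 = X0, E0 = E0,
       Su = Matrix::sparseMatrix(i = uo, j = seq_len(K), x = 1, dims = c(N, K)),
       Sv = Matrix::sparseMatrix(i = vf, j = seq_len(K), x = 1, dims = c(N, K)))
}

# Glorot-uniform weight init; biases zero. Flat named parameter list.
gnn_init_params <- function(d_node, hidden, n_layers, seed) {
  set.seed(seed)
  glorot <- function(a, b) matrix(stats::runif(a * b, -1, 1) * sqrt(6 / (a + b)), a, b)
  p <- list()
  d_in <- d_node; de <- 1L
  for (l in seq_len(n_layers)) {
    p[[sprintf("L%d_Wh", l)]] <- glorot(d_in, hidden)
    p[[sprintf("L%d_We", l)]] <- glorot(de, hidden)
    p[[sprintf("L%d_bm", l)]] <- numeric(hidden)
    p[[sprintf("L%d_Q1", l)]] <- glorot(d_in, hidden)
    p[[sprintf("L%d_Q2", l)]] <- glorot(hidden, hidden)
    p[[sprintf("L%d_bq", l)]] <- numeric(hidden)
    p[[sprintf("L%d_P1", l)]] <- glorot(de, hidden)
    p[[sprintf("L%d_P2", l)]] <- glorot(hidden, hidden)
    p[[sprintf("L%d_P3", l)]] <- glorot(hidden, hidden)
    p[[sprintf("L%d_bp", l)]] <- numeric(hidden)
    d_in <- hidden; de <- hidden
  }
  p$H_O1u <- glorot(hidden, hidden)
  p$H_O1v <- glorot(hidden, hidden)
  p$H_b1 <- numeric(hidden)
  p$H_o2 <- glorot(hidden, 1L)
  p$H_b2 <- 0
  p
}

# Forward pass over n_layers of message passing.
# keep: logical K, edges participating in message passing this epoch.
# Per layer l and directed edge j -> i (both directions of each kept edge):
#   message  m_ij = relu(h_j Wh + e_ij We + bm)
#   aggregate a_i = mean of incoming messages (0 if none)
#   node     h_i' = relu(h_i Q1 + a_i Q2 + bq)
#   edge     e'   = relu(e P1 + h_u' P2 + h_v' P3 + bp)
# Node-side linear maps are applied to the N x d embedding matrices first and
# then gathered per directed edge, so the dense GEMMs are node-sized rather
# than edge-sized. `cache = TRUE` retains intermediates for backprop;
# `update_last_edges` controls whether the (otherwise unused) last-layer edge
# update is computed.
gnn_forward <- function(params, gt, n_layers, keep = NULL, cache = FALSE,
                        update_last_edges = TRUE) {
  K <- gt$K; N <- gt$N
  if (is.null(keep)) keep <- rep(TRUE, K)
  idx <- which(keep)
  srcd <- c(gt$uo[idx], gt$vf[idx])
  dstd <- c(gt$vf[idx], gt$uo[idx])
  eidd <- c(idx, idx)
  deg <- tabulate(dstd, N)
  nd <- length(dstd)
  Agg <- Matrix::sparseMatrix(i = dstd, j = seq_len(nd),
                              x = 1 / pmax(deg[dstd], 1L), dims = c(N, nd))
  H <- gt$X0; E <- gt$E0
  caches <- if (cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    # bias folded into the node-sized factor before the per-edge gather
    HW <- add_bias(H %*% params[[sprintf("L%d_Wh", l)]],
                   params[[sprintf("L%d_bm", l)]])
    EW <- E %*% params[[sprintf("L%d_We", l)]]
    Sm <- HW[srcd, , drop = FALSE] + EW[eidd, , drop = FALSE]
    Mpos <- Sm > 0
    Md <- Sm * Mpos
    A <- as.matrix(Agg %*% Md)
    Sn <- add_bias(H %*% params[[sprintf("L%d_Q1", l)]] +
                     A %*% params[[sprintf("L%d_Q2", l)]],
                   params[[sprintf("L%d_bq", l)]])
    Npos <- Sn > 0
    Hn <- Sn * Npos
    if (l < n_layers || update_last_edges) {
      HP2 <- add_bias(Hn %*% params[[sprintf("L%d_P2", l)]],
                      params[[sprintf("L%d_bp", l)]])
      HP3 <- Hn %*% params[[sprintf("L%d_P3", l)]]
      Se <- E %*% params[[sprintf("L%d_P1", l)]] +
        HP2[gt$uo, , drop = FALSE] + HP3[gt$vf, , drop = FALSE]
      Epos <- Se > 0
      En <- Se * Epos
    } else {
      Epos <- NULL; En <- E
    }
    if (cache)
      caches[[l]] <- list(H = H, E = E, A = A, Mpos = Mpos, Npos = Npos,
                          Epos = Epos, Hn = Hn)
    H <- Hn; E <- En
  }
  list(H = H, E = E, caches = caches,
       srcd = srcd, dstd = dstd, eidd = eidd, Agg = Agg)
}

# Prediction head: scalar value for node pairs (u, v) from final embeddings.
head_predict <- function(params, H, u, v) {
  Z <- add_bias(H[u, , drop = FALSE] %*% params$H_O1u +
                  H[v, , drop = FALSE] %*% params$H_O1v, params$H_b1)
  Z <- Z * (Z > 0)
  drop(Z %*% params$H_o2) + params$H_b2
}

# Full forward + analytic backward for the MSE-on-observed-edges loss.
# Returns loss and a gradient list parallel to params. Gradients flowing
# through per-edge gathers are scatter-added back to node/edge index space
# (sparse incidence products) BEFORE the dense transforms, mirroring the
# node-sized factorization of the forward pass.
gnn_grad <- function(params, gt, n_layers, keep) {
  fw <- gnn_forward(params, gt, n_layers, keep, cache = TRUE,
                    update_last_edges = FALSE)
  Hn_f <- fw$H
  Kt <- gt$K
  Au <- add_bias(Hn_f %*% params$H_O1u, params$H_b1)
  Av <- Hn_f %*% params$H_O1v
  Zs <- Au[gt$uo, , drop = FALSE] + Av[gt$vf, , drop = FALSE]
  Zpos <- Zs > 0
  Z <- Zs * Zpos
  pred <- drop(Z %*% params$H_o2) + params$H_b2
  r <- pred - gt$y
  loss <- mean(r^2)

  g <- vector("list", length(params)); names(g) <- names(params)
  dpred <- matrix(2 * r / Kt, ncol = 1)
  g$H_o2 <- crossprod(Z, dpred)
  g$H_b2 <- sum(dpred)
  dZ <- (dpred %*% t(params$H_o2)) * Zpos
  sU_dZ <- as.matrix(gt$Su %*% dZ)
  sV_dZ <- as.matrix(gt$Sv %*% dZ)
  g$H_O1u <- crossprod(Hn_f, sU_dZ)
  g$H_O1v <- crossprod(Hn_f, sV_dZ)
  g$H_b1 <- colSums(dZ)
  dHn <- tcrossprod(sU_dZ, params$H_O1u) + tcrossprod(sV_dZ, params$H_O1v)
  dEn <- NULL   # last-layer edge embeddings do not feed the loss

  tAgg <- Matrix::t(fw$Agg)
  nd <- length(fw$srcd)
  Ssrc_sum <- Matrix::sparseMatrix(i = fw$srcd, j = seq_len(nd), x = 1,
                                   dims = c(gt$N, nd))
  Seid_sum <- Matrix::sparseMatrix(i = fw$eidd, j = seq_len(nd), x = 1,
                                   dims = c(gt$K, nd))

  for (l in rev(seq_len(n_layers))) {
    cc <- fw$caches[[l]]
    if (!is.null(dEn)) {
      dSe <- dEn * cc$Epos
      sU_dSe <- as.matrix(gt$Su %*% dSe)
      sV_dSe <- as.matrix(gt$Sv %*% dSe)
      g[[sprintf("L%d_P1", l)]] <- crossprod(cc$E, dSe)
      g[[sprintf("L%d_P2", l)]] <- crossprod(cc$Hn, sU_dSe)
      g[[sprintf("L%d_P3", l)]] <- crossprod(cc$Hn, sV_dSe)
      g[[sprintf("L%d_bp", l)]] <- colSums(dSe)
      dE_in <- tcrossprod(dSe, params[[sprintf("L%d_P1", l)]])
      dHn <- dHn + tcrossprod(sU_dSe, params[[sprintf("L%d_P2", l)]]) +
        tcrossprod(sV_dSe, params[[sprintf("L%d_P3", l)]])
    } else {
      h <- ncol(dHn)
      de_in <- ncol(cc$E)
      g[[sprintf("L%d_P1", l)]] <- matrix(0, de_in, h)
      g[[sprintf("L%d_P2", l)]] <- matrix(0, h, h)
      g[[sprintf("L%d_P3", l)]] <- matrix(0, h, h)
      g[[sprintf("L%d_bp", l)]] <- numeric(h)
      dE_in <- matrix(0, gt$K, de_in)
    }
    dSn <- dHn * cc$Npos
    g[[sprintf("L%d_Q1", l)]] <- crossprod(cc$H, dSn)
    g[[sprintf("L%d_Q2", l)]] <- crossprod(cc$A, dSn)
    g[[sprintf("L%d_bq", l)]] <- colSums(dSn)
    dH_in <- tcrossprod(dSn, params[[sprintf("L%d_Q1", l)]])
    dA <- tcrossprod(dSn, params[[sprintf("L%d_Q2", l)]])
    dMd <- as.matrix(tAgg %*% dA)
    dSm <- dMd * cc$Mpos
    sSrc_dSm <- as.matrix(Ssrc_sum %*% dSm)
    sEid_dSm <- as.matrix(Seid_sum %*% dSm)
    g[[sprintf("L%d_Wh", l)]] <- crossprod(cc$H, sSrc_dSm)
    g[[sprintf("L%d_We", l)]] <- crossprod(cc$E, sEid_dSm)
    g[[sprintf("L%d_bm", l)]] <- colSums(dSm)
    dH_in <- dH_in + tcrossprod(sSrc_dSm, params[[sprintf("L%d_Wh", l)]])
    dE_in <- dE_in + tcrossprod(sEid_dSm, params[[sprintf("L%d_We", l)]])
    dHn <- dH_in
    dEn <- dE_in
  }
  list(loss = loss, grads = g, pred = pred)
}

# one Adam update over the flat parameter list (in place semantics via return)
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = Inf) {
  if (is.finite(clip)) {
    gn <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
    if (gn > clip) grads <- lapply(grads, function(x) x * (clip / gn))
  }
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the GNN imputer on a joint bipartite graph
#'
#' Full-batch training that minimizes mean squared error between predicted and
#' observed scaled values over the observed edges. Each epoch an independent
#' edge-dropout draw removes a fraction of observed edges from message passing
#' while keeping them as prediction targets. Training is deterministic given
#' `config$seed`.
#'
#' @param graph a [build_graph()] result.
#' @param config an [imputer_config()].
#' @return an object of class `trained_imputer`: `params`, `loss_trace`
#'   (length `epochs`), `config`, `d_node` (input node-feature width),
#'   `feature_names`.
#' @export
train_imputer <- function(graph, config = imputer_config()) {
  stopifnot(inherits(graph, "bipartite_graph"), inherits(config, "imputer_config"))
  gt <- graph_tensors(graph)
  if (gt$K < 1) stop("graph has no observed edges")
  params <- gnn_init_params(gt$n, config$hidden_dim, config$n_layers,
                            derive_seed(config$seed, "init"))
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  loss_trace <- numeric(config$epochs)
  set.seed(derive_seed(config$seed, "dropout"))
  for (epoch in seq_len(config$epochs)) {
    keep <- if (config$edge_dropout > 0)
      stats::runif(gt$K) >= config$edge_dropout else rep(TRUE, gt$K)
    if (!any(keep)) keep <- rep(TRUE, gt$K)
    fg <- gnn_grad(params, gt, config$n_layers, keep)
    if (!is.finite(fg$loss))
      stop("non-finite training loss; consider a lower learning rate")
    upd <- adam_step(params, fg$grads, state, config$learning_rate, epoch,
                     clip = config$grad_clip)
    params <- upd$params; state <- upd$state
    loss_trace[epoch] <- fg$loss
  }
  structure(list(params = params, loss_trace = loss_trace, config = config,
                 d_node = gt$n, feature_names = graph$feature_names),
            class = "trained_imputer")
}

#' @export
print.trained_imputer <- function(x, ...) {
  cat(sprintf("<trained_imputer> %d layers x %d hidden, %d epochs, final train MSE %.5f\n",
              x$config$n_layers, x$config$hidden_dim,
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Final node and edge embeddings of a graph under given parameters
#'
#' Runs the full message-passing stack (no dropout) and returns the
#' hidden-dimension embeddings of every node and every observed edge.
#'
#' @param graph a `bipartite_graph`.
#' @param model a `trained_imputer` (or a raw parameter list with matching
#'   shapes, in which case `n_layers` must be supplied).
#' @param n_layers number of layers when `model` is a raw parameter list.
#' @return list with `node_embeddings` (`(m+n) x hidden`; observation nodes
#'   first) and `edge_embeddings` (`K x hidden`, in the graph's edge order).
#' @export
gnn_forward_pass <- function(graph, model, n_layers = NULL) {
  params <- if (inherits(model, "trained_imputer")) model$params else model
  nl <- if (inherits(model, "trained_imputer")) model$config$n_layers else n_layers
  if (is.null(nl)) stop("n_layers required for a raw parameter list")
  gt <- graph_tensors(graph)
  fw <- gnn_forward(params, gt, nl)
  list(node_embeddings = fw$H, edge_embeddings = fw$E)
}

#' Predict edge values for arbitrary (observation, feature) node pairs
#'
#' @param graph the `bipartite_graph` the embeddings come from.
#' @param model a `trained_imputer`.
#' @param pairs two-column matrix/data.frame: observation node (1..m) and
#'   feature node (1..n) indices.
#' @return numeric vector of predicted scaled values.
#' @export
gnn_predict_edges <- function(graph, model, pairs) {
  stopifnot(inherits(model, "trained_imputer"))
  pairs <- as.matrix(pairs)
  gt <- graph_tensors(graph)
  if (any(pairs[, 1] < 1 | pairs[, 1] > gt$m) ||
      any(pairs[, 2] < 1 | pairs[, 2] > gt$n))
    stop("unknown node id in pairs")
  fw <- gnn_forward(model$params, gt, model$config$n_layers)
  head_predict(model$params, fw$H, pairs[, 1], gt$m + pairs[, 2])
}

#' Impute every cell of a graph's design matrix with a trained model
#'
#' Predicts a value for all `M x F` (observation, feature) pairs, then
#' overwrites observed cells with their known values (observed passthrough).
#' The model is inductive: `graph` need not be the training graph, as long as
#' the feature schema matches.
#'
#' @param model a `trained_imputer`.
#' @param graph a `bipartite_graph` with the same feature count/order as the
#'   training graph.
#' @return an object of class `imputation_result`: `predicted` (`M x F`, all
#'   finite), `observed_mask` (`M x F` logical, `TRUE` where the cell was a
#'   training edge).
#' @export
impute_graph <- function(model, graph) {
  stopifnot(inherits(model, "trained_imputer"), inherits(graph, "bipartite_graph"))
  if (graph$n_feat != model$d_node ||
      !identical(graph$feature_names, model$feature_names))
    stop("feature schema mismatch between model and graph")
  gt <- graph_tensors(graph)
  fw <- gnn_forward(model$params, gt, model$config$n_layers)
  m <- gt$m; n <- gt$n
  Au <- fw$H[seq_len(m), , drop = FALSE] %*% model$params$H_O1u
  Bv <- fw$H[m + seq_len(n), , drop = FALSE] %*% model$params$H_O1v
  pred <- matrix(NA_real_, m, n, dimnames = list(NULL, graph$feature_names))
  for (f in seq_len(n)) {
    Z <- add_bias(Au, model$params$H_b1 + Bv[f, ])
    Z <- Z * (Z > 0)
    pred[, f] <- drop(Z %*% model$params$H_o2) + model$params$H_b2
  }
  if (any(!is.finite(pred))) stop("non-finite imputed values")
  obs_mask <- matrix(FALSE, m, n)
  obs_mask[cbind(gt$uo, gt$vf - m)] <- TRUE
  raw <- pred
  pred[cbind(gt$uo, gt$vf - m)] <- gt$y
  structure(list(predicted = pred, observed_mask = obs_mask, raw = raw),
            class = "imputation_result")
}
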