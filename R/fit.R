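#' Fit the temporal-setting graph imputation model
#'
#' The main entry point of the package. The input series is cut into
#' stride-1 sliding windows of length `sequence_length`, flattened into the
#' observation-node design matrix, represented as a joint bipartite graph
#' (observed cells = attributed edges), and a GraphSAGE-style GNN with edge
#' embeddings is trained to predict every cell from the observed edges. The
#' multiple window copies of each source cell are then reconciled (mean by
#' default) to yield the imputed series. With `sequence_length = NULL` the
#' windowing step is skipped (each source row is its own observation node),
#' which reproduces the static, non-temporal bipartite representation and is
#' the natural baseline for the windowed model.
#'
#' @param x a `temporal_series` (or matrix/data.frame), or an
#'   `entity_collection` for irregular multi-entity data. Missing cells `NA`.
#' @param sequence_length window length L (`1 <= L < T`). `NULL` disables
#'   windowing; `"auto"` (collections only) uses
#'   [determine_sequence_length()].
#' @param config an [imputer_config()].
#' @param normalize `"minmax"` (default), `"zscore"`, or `"none"` if `x` is
#'   already scaled. Statistics are computed on observed cells and stored for
#'   inductive reuse by [predict.tsi_gnn()].
#' @param min_length minimum entity length for `"auto"` sequence length.
#' @param reducer how window copies of a cell are reconciled: `"mean"`,
#'   `"first"` or `"median"`.
#' @param threshold size budget for the graph (number of design-matrix cells,
#'   `(T - L) * L * F` when fully observed); default four million.
#' @param force train even when the estimated size exceeds the threshold.
#' @return an object of class `tsi_gnn`; see [print.tsi_gnn()],
#'   [summary.tsi_gnn()], [fitted.tsi_gnn()], [predict.tsi_gnn()],
#'   [residuals.tsi_gnn()], [plot.tsi_gnn()], [imputed_series()].
#' @examples
#' \donttest{
#' ts <- generate_regular(synth_spec(n_timesteps = 60, n_features = 3, seed = 2))
#' masked <- apply_mcar_mask(ts, 0.3, seed = 9, label_protected = FALSE)
#' fit <- tsi_gnn(masked$masked, sequence_length = 5,
#'                config = imputer_config(epochs = 50, hidden_dim = 16, seed = 1))
#' fit
#' }
#' @export
tsi_gnn <- function(x, sequence_length = NULL, config = imputer_config(),
                    normalize = c("minmax", "zscore", "none"),
                    min_length = 9, reducer = "mean",
                    threshold = 4e6, force = FALSE) {
  cl <- match.call()
  normalize <- match.arg(normalize)
  is_collection <- inherits(x, "entity_collection")
  if (!is_collection) x <- as_temporal_series(x)

  # -- normalization (on observed cells of the input) --------------------------
  norm_stats <- NULL
  xs <- x
  if (normalize != "none") {
    nm <- normalize_series(x, method = normalize)
    xs <- nm$series
    norm_stats <- nm$stats
  }

  # -- windowing ---------------------------------------------------------------
  if (is_collection) {
    L <- sequence_length
    if (is.null(L) || identical(L, "auto"))
      L <- determine_sequence_length(x, min_length = min_length)
    flat <- window_collection(xs, L)
  } else if (is.null(sequence_length)) {
    L <- NA_integer_   # non-windowed, static bipartite representation
    T_ <- nrow(xs$values)
    flat <- structure(list(values = xs$values,
                           row_provenance = data.frame(window = 0:(T_ - 1L),
                                                       step = 0L,
                                                       source_row = 0:(T_ - 1L)),
                           sequence_length = 1L,
                           source_shape = dim(xs$values),
                           feature_names = xs$feature_names,
                           feature_kinds = xs$feature_kinds,
                           entity_id = xs$entity_id),
                      class = "flat_design")
  } else {
    L <- as.integer(sequence_length)
    flat <- flatten_windows(cut_windows(xs, L))
  }

  # -- size gate ---------------------------------------------------------------
  size <- nrow(flat$values) * ncol(flat$values)
  est <- structure(list(size = size, threshold = threshold,
                        within_budget = size <= threshold),
                   class = "size_estimate")
  if (!est$within_budget && !force)
    stop(sprintf(paste0("estimated model size %d exceeds threshold %d; ",
                        "reduce sequence_length/features or use force = TRUE"),
                 size, as.integer(threshold)))

  # -- graph + training --------------------------------------------------------
  graph <- build_graph(flat)
  model <- train_imputer(graph, config)
  res <- impute_graph(model, graph)

  # -- collapse back to the source shape --------------------------------------
  flat_imp <- flat
  flat_imp$values <- res$predicted
  if (is_collection) {
    collapsed <- collapse_collection(flat_imp, xs, reducer = reducer)
    collapsed <- passthrough_and_fill_collection(collapsed, xs)
  } else {
    collapsed <- collapse_to_series(flat_imp, xs, reducer = reducer,
                                    uncovered = "pass")
    collapsed$values[!is.na(xs$values)] <- xs$values[!is.na(xs$values)]
    collapsed$values <- fill_remaining(collapsed$values)
  }
  imputed <- if (is.null(norm_stats)) collapsed
             else denormalize_series(collapsed, norm_stats)

  structure(list(call = cl, config = config, sequence_length = L,
                 windowed = !is.na(L) || is_collection,
                 size_estimate = est, norm_method = normalize,
                 norm_stats = norm_stats, model = model,
                 graph_summary = list(n_obs = graph$n_obs,
                                      n_feat = graph$n_feat,
                                      n_edges = nrow(graph$edges)),
                 loss_trace = model$loss_trace,
                 imputed = imputed, imputed_scaled = collapsed,
                 residual_edges = res$raw[cbind(graph$edges$obs, graph$edges$feat)] -
                   graph$edges$value,
                 input_missing = if (is_collection)
                   lapply(x$series, function(s) is.na(s$values))
                 else is.na(x$values),
                 reducer = reducer,
                 is_collection = is_collection),
            class = "tsi_gnn")
}

# carry the nearest imputed/observed value along time for cells left NA (rows
# outside every window: the final source row, and truncated-away rows of long
# entities); last resort is the feature column mean
fill_remaining <- function(vals) {
  for (f in seq_len(ncol(vals))) {
    mis <- which(is.na(vals[, f]))
    if (!length(mis)) next
    obs <- which(!is.na(vals[, f]))
    if (!length(obs)) { vals[, f] <- 0; next }
    for (i in mis) vals[i, f] <- vals[obs[which.min(abs(obs - i))], f]
  }
  vals
}

passthrough_and_fill_collection <- function(collapsed, source_scaled) {
  for (id in names(collapsed$series)) {
    sv <- source_scaled$series[[id]]$values
    cv <- collapsed$series[[id]]$values
    cv[!is.na(sv)] <- sv[!is.na(sv)]
    collapsed$series[[id]]$values <- fill_remaining(cv)
  }
  collapsed
}

#' Extract the imputed series from a fit
#' @param fit a `tsi_gnn` object.
#' @param scale `"original"` (default) or `"scaled"` (the normalized space the
#'   model was trained and evaluated in).
#' @return a `temporal_series` or `entity_collection` with no missing cells.
#' @export
imputed_series <- function(fit, scale = c("original", "scaled")) {
  stopifnot(inherits(fit, "tsi_gnn"))
  scale <- match.arg(scale)
  if (scale == "original") fit$imputed else fit$imputed_scaled
}

#' @export
print.tsi_gnn <- function(x, ...) {
  cat("Temporal-setting graph imputation model\n")
  cat(sprintf("  representation: %s\n",
              if (x$windowed) sprintf("joint bipartite graph, sequence length %s",
                                      x$sequence_length)
              else "static bipartite graph (non-windowed)"))
  cat(sprintf("  graph: %d observation nodes, %d feature nodes, %d observed edges\n",
              x$graph_summary$n_obs, x$graph_summary$n_feat, x$graph_summary$n_edges))
  cat(sprintf("  size: %s (threshold %s)\n",
              format(x$size_estimate$size, big.mark = ",", scientific = FALSE),
              format(x$size_estimate$threshold, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  training: %d epochs, final MSE %.5f\n",
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.tsi_gnn <- function(object, ...) {
  n_missing <- if (object$is_collection)
    sum(vapply(object$input_missing, sum, numeric(1)))
  else sum(object$input_missing)
  s <- list(config = object$config, graph = object$graph_summary,
            size = object$size_estimate,
            sequence_length = object$sequence_length,
            loss_first = object$loss_trace[1],
            loss_last = utils::tail(object$loss_trace, 1),
            n_missing_imputed = n_missing,
            resid_rmse = sqrt(mean(object$residual_edges^2)))
  class(s) <- "summary.tsi_gnn"
  s
}

#' @export
print.summary.tsi_gnn <- function(x, ...) {
  cat("Temporal-setting graph imputation model\n")
  cat(sprintf("  layers %d, hidden %d, aggregation %s, lr %g, edge dropout %g\n",
              x$config$n_layers, x$config$hidden_dim, x$config$aggregation,
              x$config$learning_rate, x$config$edge_dropout))
  cat(sprintf("  sequence length: %s\n", x$sequence_length))
  cat(sprintf("  graph: %d obs nodes / %d feature nodes / %d edges (size %s)\n",
              x$graph$n_obs, x$graph$n_feat, x$graph$n_edges,
              format(x$size$size, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  train MSE: %.5f -> %.5f over %d epochs\n",
              x$loss_first, x$loss_last, x$config$epochs))
  cat(sprintf("  observed-edge RMSE (scaled): %.5f\n", x$resid_rmse))
  cat(sprintf("  missing cells imputed: %d\n", x$n_missing_imputed))
  invisible(x)
}

#' @export
coef.tsi_gnn <- function(object, ...) object$model$params

#' @export
fitted.tsi_gnn <- function(object, ...) {
  if (object$is_collection) object$imputed
  else object$imputed$values
}

#' Residuals on observed edges
#'
#' Raw model predictions minus observed scaled values over the training
#' (observed) edges of the graph, before observed-value passthrough.
#'
#' @param object a `tsi_gnn` fit.
#' @param ... unused.
#' @return numeric vector, one element per observed edge.
#' @export
residuals.tsi_gnn <- function(object, ...) object$residual_edges

#' Plot the training-loss trace
#' @param x a `tsi_gnn` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tsi_gnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "train MSE (observed edges)",
                 main = "GNN imputer training loss", ...)
  invisible(x)
}

#' Impute new data with a fitted model (inductive use)
#'
#' Builds a graph from `newdata` (normalized with the training statistics,
#' windowed at the fitted sequence length) and predicts its cells with the
#' trained parameters — no retraining. The feature schema must match.
#'
#' @param object a `tsi_gnn` fit.
#' @param newdata a `temporal_series`/matrix or `entity_collection`; when
#'   omitted, the training-data imputation is returned.
#' @param ... unused.
#' @return an imputed series on the original scale.
#' @export
predict.tsi_gnn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$imputed)
  is_collection <- inherits(newdata, "entity_collection")
  if (!is_collection) newdata <- as_temporal_series(newdata)
  xs <- if (is.null(object$norm_stats)) newdata
        else normalize_series(newdata, stats = object$norm_stats)$series
  if (is_collection) {
    L <- object$sequence_length
    flat <- window_collection(xs, L)
  } else if (!object$windowed) {
    T_ <- nrow(xs$values)
    flat <- structure(list(values = xs$values,
                           row_provenance = data.frame(window = 0:(T_ - 1L),
                                                       step = 0L,
                                                       source_row = 0:(T_ - 1L)),
                           sequence_length = 1L, source_shape = dim(xs$values),
                           feature_names = xs$feature_names,
                           feature_kinds = xs$feature_kinds,
                           entity_id = xs$entity_id),
                      class = "flat_design")
  } else {
    flat <- flatten_windows(cut_windows(xs, object$sequence_length))
  }
  graph <- build_graph(flat)
  res <- impute_graph(object$model, graph)
  flat$values <- res$predicted
  if (is_collection) {
    collapsed <- collapse_collection(flat, xs, reducer = object$reducer)
    collapsed <- passthrough_and_fill_collection(collapsed, xs)
  } else {
    collapsed <- collapse_to_series(flat, xs, reducer = object$reducer,
                                    uncovered = "pass")
    collapsed$values[!is.na(xs$values)] <- xs$values[!is.na(xs$values)]
    collapsed$values <- fill_remaining(collapsed$values)
  }
  if (is.null(object$norm_stats)) collapsed
  else denormalize_series(collapsed, object$norm_stats)
}
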