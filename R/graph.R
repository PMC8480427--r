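#' Estimate the size of a joint bipartite graph before building it
#'
#' The number of trainable edges of a fully observed joint bipartite graph is
#' `(T - L) * L * F`: windows times window length gives the observation-node
#' count, and each observation node connects to every feature node. Knowing
#' the size in advance lets the user balance `L` and `F` against a hardware
#' budget; a size of at most four million is practical on a laptop-class
#' machine, hence the default threshold.
#'
#' @param observations number of source timesteps T.
#' @param sequence_length window length L (must satisfy `T > L >= 1`).
#' @param features number of features F.
#' @param threshold nonnegative size budget (default `4e6`).
#' @return an object of class `size_estimate`: list with `size`, `threshold`,
#'   `within_budget` (`size <= threshold`, inclusive).
#' @examples
#' estimate_size(4120, 21, 6)   # 516474, within budget
#' @export
estimate_size <- function(observations, sequence_length, features,
                          threshold = 4e6) {
  T_ <- observations; L <- sequence_length; F_ <- features
  if (L < 1 || F_ < 1) stop("sequence_length and features must be >= 1")
  if (T_ <= L) stop("observations must exceed sequence_length")
  if (threshold < 0) stop("threshold must be nonnegative")
  size <- (T_ - L) * L * F_
  structure(list(size = size, threshold = threshold,
                 within_budget = size <= threshold),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("<size_estimate> size = %s, threshold = %s: %s\n",
              format(x$size, big.mark = ",", scientific = FALSE), format(x$threshold, big.mark = ",", scientific = FALSE),
              if (x$within_budget) "within budget" else "OVER BUDGET"))
  invisible(x)
}

#' Check a proposed model against the size budget
#'
#' Thin wrapper over [estimate_size()] used as a hard gate by the command-line
#' interface: training is refused when `within_budget` is `FALSE` unless
#' overridden.
#'
#' @inheritParams estimate_size
#' @return a `size_estimate`.
#' @export
check_budget <- function(observations, sequence_length, features,
                         threshold = 4e6) {
  estimate_size(observations, sequence_length, features, threshold)
}

#' Build the joint bipartite graph from a flat design matrix
#'
#' One observation node per flat row, one feature node per feature, and one
#' attributed undirected edge per observed (non-missing) cell carrying the
#' scaled value. No observation-observation or feature-feature edges exist:
#' temporal structure enters only through the window layout of the observation
#' nodes ("ghost" edges). Initial embeddings follow the reference
#' architecture: feature node f gets the F-dimensional one-hot of f,
#' observation nodes get the all-ones vector of dimension F.
#'
#' @param flat a `flat_design` whose values are already normalized; missing
#'   cells are `NA`.
#' @param feature_kinds optional per-feature tags overriding those in `flat`.
#' @return an object of class `bipartite_graph`: `n_obs`, `n_feat`, `edges`
#'   (data.frame `obs`, `feat` (1-based), `value`, `kind`), `feature_names`,
#'   `sequence_length`, `provenance`, `source_shape`.
#' @export
build_graph <- function(flat, feature_kinds = NULL) {
  stopifnot(inherits(flat, "flat_design"))
  vals <- flat$values
  M <- nrow(vals); F_ <- ncol(vals)
  if (is.null(feature_kinds)) feature_kinds <- flat$feature_kinds
  feature_kinds <- rep_len(feature_kinds, F_)
  obs_cells <- which(!is.na(vals), arr.ind = TRUE)
  if (nrow(obs_cells) == 0L) stop("empty graph: no observed cells")
  v <- vals[obs_cells]
  if (any(!is.finite(v))) stop("edge values must be finite")
  edges <- data.frame(obs = obs_cells[, 1L], feat = obs_cells[, 2L],
                      value = v, kind = feature_kinds[obs_cells[, 2L]])
  # deterministic edge order: by observation node then feature
  edges <- edges[order(edges$obs, edges$feat), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_obs = M, n_feat = F_, edges = edges,
                 feature_names = flat$feature_names,
                 feature_kinds = feature_kinds,
                 sequence_length = flat$sequence_length,
                 provenance = flat$row_provenance,
                 source_shape = flat$source_shape),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d observation nodes, %d feature nodes, %d edges (L = %d)\n",
              x$n_obs, x$n_feat, nrow(x$edges), x$sequence_length))
  invisible(x)
}

#' Serialize a bipartite graph to an edge-list directory
#'
#' Writes `edges.csv` (`u_id, v_id, value`; `u_id` are observation nodes
#' `0..m-1`, `v_id` are feature nodes `m..m+n-1`) and a JSON sidecar
#' `meta.json` with shapes, sequence length and the feature schema.
#'
#' @param graph a `bipartite_graph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "bipartite_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- data.frame(u_id = graph$edges$obs - 1L,
                   v_id = graph$n_obs + graph$edges$feat - 1L,
                   value = graph$edges$value)
  utils::write.csv(el, file.path(dir, "edges.csv"), row.names = FALSE)
  meta <- list(n_obs = graph$n_obs, n_feat = graph$n_feat,
               sequence_length = graph$sequence_length,
               source_shape = graph$source_shape,
               feature_names = graph$feature_names,
               feature_kinds = graph$feature_kinds)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a bipartite graph written by [write_graph()]
#' @param dir directory containing `edges.csv` and `meta.json`.
#' @return a `bipartite_graph` (without provenance).
#' @export
read_graph <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  el <- utils::read.csv(file.path(dir, "edges.csv"))
  edges <- data.frame(obs = el$u_id + 1L, feat = el$v_id - meta$n_obs + 1L,
                      value = el$value,
                      kind = meta$feature_kinds[el$v_id - meta$n_obs + 1L])
  edges <- edges[order(edges$obs, edges$feat), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_obs = meta$n_obs, n_feat = meta$n_feat, edges = edges,
                 feature_names = meta$feature_names,
                 feature_kinds = meta$feature_kinds,
                 sequence_length = meta$sequence_length,
                 provenance = NULL, source_shape = meta$source_shape),
            class = "bipartite_graph")
}
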