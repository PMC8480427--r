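# shared fixture builders; everything is generated in code under fixed seeds

random_series <- function(T_, F_, seed = 1, missing_rate = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(T_ * F_), T_, F_)
  if (missing_rate > 0)
    vals[matrix(runif(T_ * F_) < missing_rate, T_, F_)] <- NA_real_
  temporal_series(vals)
}

# flat_design with one observation node per row (no windowing) — handy for
# exercising the graph/GNN layers with exactly controlled cell patterns
identity_flat <- function(vals) {
  T_ <- nrow(vals)
  if (is.null(colnames(vals))) colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  structure(list(values = vals,
                 row_provenance = data.frame(window = 0:(T_ - 1L), step = 0L,
                                             source_row = 0:(T_ - 1L)),
                 sequence_length = 1L, source_shape = dim(vals),
                 feature_names = colnames(vals),
                 feature_kinds = rep("continuous", ncol(vals)),
                 entity_id = NULL),
            class = "flat_design")
}

# collection with given per-entity lengths, shared schema
lengths_collection <- function(lens, F_ = 1, seed = 1) {
  set.seed(seed)
  series <- lapply(seq_along(lens), function(i)
    temporal_series(matrix(rnorm(lens[i] * F_), lens[i], F_),
                    entity_id = as.character(i)))
  names(series) <- as.character(seq_along(lens))
  entity_collection(series)
}
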