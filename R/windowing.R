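#' Cut a temporal series into sliding windows
#'
#' Applies a stride-1 sliding window of length `sequence_length` (L) to the
#' `T x F` series, producing `W = T - L` windows: window `w` (0-based) covers
#' source rows `w .. w+L-1`. Note the window count is `T - L`, not the usual
#' `T - L + 1`: the joint-bipartite construction drops one admissible window,
#' so the final source row is covered by no window (see
#' [collapse_to_series()]). Missing cells are carried through unchanged.
#'
#' @param series a [temporal_series()] (or coercible).
#' @param sequence_length window length L, a positive integer with L < T.
#' @return an object of class `windowed_tensor` with fields `values`
#'   (`W x L x F` array), `window_starts` (0-based, equal to `0:(W-1)`),
#'   `sequence_length`, `source_shape = c(T, F)`, `feature_names`.
#' @examples
#' ts <- temporal_series(matrix(1:10, 5, 2))
#' cut_windows(ts, 2)$values |> dim()   # 3 x 2 x 2
#' @export
cut_windows <- function(series, sequence_length) {
  series <- as_temporal_series(series)
  L <- sequence_length
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stop("sequence_length must be a positive integer")
  L <- as.integer(L)
  T_ <- nrow(series$values); F_ <- ncol(series$values)
  if (L >= T_) stop("series shorter than sequence length")
  W <- T_ - L
  arr <- array(NA_real_, dim = c(W, L, F_))
  for (s in seq_len(L)) arr[, s, ] <- series$values[s:(s + W - 1L), , drop = FALSE]
  structure(list(values = arr, window_starts = 0:(W - 1L), sequence_length = L,
                 source_shape = c(T_, F_), feature_names = series$feature_names,
                 feature_kinds = series$feature_kinds, entity_id = series$entity_id),
            class = "windowed_tensor")
}

#' Flatten a windowed tensor into the observation-node design matrix
#'
#' Reshapes the `W x L x F` windowed array row-major over `(window, step)` into
#' an `M x F` matrix with `M = W * L`. Row `k` (0-based) of the flat matrix is
#' step `k mod L` of window `k div L`, i.e. source row `(k div L) + (k mod L)`.
#' Each flat row becomes one observation node of the joint bipartite graph;
#' the flattening preserves sequence-length information in the row layout.
#'
#' @param windowed a `windowed_tensor` from [cut_windows()].
#' @return an object of class `flat_design` with fields `values` (`M x F`),
#'   `row_provenance` (data.frame with 0-based `window`, `step`, `source_row`),
#'   `sequence_length`, `source_shape`, `feature_names`.
#' @export
flatten_windows <- function(windowed) {
  stopifnot(inherits(windowed, "windowed_tensor"))
  d <- dim(windowed$values)
  W <- d[1]; L <- d[2]; F_ <- d[3]
  # (W,L,F) -> permute to (L,W,F) so column-major unrolling walks step fastest
  flat <- matrix(aperm(windowed$values, c(2, 1, 3)), nrow = W * L, ncol = F_)
  colnames(flat) <- windowed$feature_names
  win <- rep(0:(W - 1L), each = L)
  step <- rep(0:(L - 1L), times = W)
  prov <- data.frame(window = win, step = step,
                     source_row = windowed$window_starts[win + 1L] + step)
  structure(list(values = flat, row_provenance = prov, sequence_length = L,
                 source_shape = windowed$source_shape,
                 feature_names = windowed$feature_names,
                 feature_kinds = windowed$feature_kinds,
                 entity_id = windowed$entity_id),
            class = "flat_design")
}

#' Restore the windowed tensor from a flat design matrix
#'
#' Exact (bit-identical) inverse of [flatten_windows()].
#'
#' @param flat a `flat_design`.
#' @return a `windowed_tensor`.
#' @export
restore_windows <- function(flat) {
  stopifnot(inherits(flat, "flat_design"))
  L <- flat$sequence_length
  M <- nrow(flat$values); F_ <- ncol(flat$values)
  if (M %% L != 0L) stop("flat row count not divisible by sequence_length")
  W <- M %/% L
  arr <- aperm(array(flat$values, dim = c(L, W, F_)), c(2, 1, 3))
  structure(list(values = arr, window_starts = 0:(W - 1L), sequence_length = L,
                 source_shape = flat$source_shape, feature_names = flat$feature_names,
                 feature_kinds = flat$feature_kinds, entity_id = flat$entity_id),
            class = "windowed_tensor")
}

#' Collapse an (imputed) flat design matrix back onto the source series
#'
#' After imputation each source cell `(t, f)` has up to L imputed copies (one
#' per window containing row `t`); this reconciles them with `reducer`. Source
#' rows represented in no window raise an error by default; with
#' `uncovered = "pass"` such rows keep their source values (missing cells stay
#' missing for the caller to handle).
#'
#' @param flat_imputed a `flat_design` whose `values` hold imputed copies.
#' @param source the original `temporal_series` (for shape, time index and
#'   uncovered-row passthrough).
#' @param reducer one of `"mean"`, `"first"`, `"median"`.
#' @param uncovered `"error"` (default) or `"pass"`.
#' @return a `temporal_series` of the source's shape.
#' @export
collapse_to_series <- function(flat_imputed, source,
                               reducer = c("mean", "first", "median"),
                               uncovered = c("error", "pass")) {
  stopifnot(inherits(flat_imputed, "flat_design"))
  source <- as_temporal_series(source)
  reducer <- match.arg(reducer)
  uncovered <- match.arg(uncovered)
  T_ <- nrow(source$values); F_ <- ncol(source$values)
  prov <- flat_imputed$row_provenance
  keep <- !is.na(prov$source_row)           # padded steps map to no source row
  vals <- flat_imputed$values[keep, , drop = FALSE]
  srow <- prov$source_row[keep] + 1L        # to 1-based
  out <- matrix(NA_real_, T_, F_, dimnames = list(NULL, source$feature_names))
  covered <- sort(unique(srow))
  if (length(covered) < T_) {
    if (uncovered == "error")
      stop("row not represented in any window")
    miss_rows <- setdiff(seq_len(T_), covered)
    out[miss_rows, ] <- source$values[miss_rows, , drop = FALSE]
  }
  if (reducer == "mean") {
    sums <- rowsum(vals, group = srow)
    cnt <- as.vector(rowsum(rep(1, length(srow)), group = srow))
    out[covered, ] <- sums / cnt
  } else {
    ord <- order(srow, prov$window[keep])   # window order defines "first"
    vs <- vals[ord, , drop = FALSE]
    gs <- srow[ord]
    idx <- split(seq_along(gs), gs)
    red <- if (reducer == "first") function(m) m[1L, ] else
      function(m) apply(m, 2, stats::median)
    for (g in names(idx)) out[as.integer(g), ] <- red(vs[idx[[g]], , drop = FALSE])
  }
  temporal_series(out, time_index = source$time_index,
                  feature_names = source$feature_names,
                  feature_kinds = source$feature_kinds,
                  entity_id = source$entity_id)
}

#' Choose the sequence length for an irregular multi-entity collection
#'
#' Entities shorter than `min_length` are excluded, then the sequence length is
#' the rounded mean of the remaining per-entity lengths (rounding half away
#' from zero). The same value serves as the per-entity maximum (truncation
#' cap) when the collection is windowed.
#'
#' @param collection an [entity_collection()].
#' @param min_length minimum per-entity length for inclusion (default 9).
#' @return a positive integer sequence length.
#' @examples
#' col <- entity_collection(list(a = temporal_series(matrix(0, 9, 1)),
#'                               b = temporal_series(matrix(0, 21, 1))))
#' determine_sequence_length(col)  # 15
#' @export
determine_sequence_length <- function(collection, min_length = 9) {
  stopifnot(inherits(collection, "entity_collection"))
  lens <- vapply(collection$series, function(s) nrow(s$values), integer(1))
  lens <- lens[lens >= min_length]
  if (!length(lens)) stop("no entity meets the minimum sequence length")
  as.integer(floor(mean(lens) + 0.5))
}

# Window every entity of a collection at sequence length L and stack the flat
# design matrices. Per-entity rule: entities with T > L+1 are truncated to
# their most recent L+1 rows (one window); entities with T <= L contribute a
# single window front-padded with missing rows (padded cells have source_row
# NA and generate no edges). Returns a flat_design whose provenance carries an
# `entity` column; source_row is 0-based within the entity's ORIGINAL series.
window_collection <- function(collection, sequence_length) {
  stopifnot(inherits(collection, "entity_collection"))
  L <- as.integer(sequence_length)
  parts <- lapply(names(collection$series), function(id) {
    s <- collection$series[[id]]
    T_ <- nrow(s$values); F_ <- ncol(s$values)
    if (T_ > L) {
      offset <- max(0L, T_ - (L + 1L))           # keep most recent L+1 rows
      sub <- temporal_series(s$values[(offset + 1L):T_, , drop = FALSE],
                             feature_names = s$feature_names,
                             feature_kinds = s$feature_kinds, entity_id = id)
      fl <- flatten_windows(cut_windows(sub, L))
      fl$row_provenance$source_row <- fl$row_provenance$source_row + offset
    } else {
      pad <- L - T_
      vals <- rbind(matrix(NA_real_, pad, F_), s$values)
      prov <- data.frame(window = 0L, step = 0:(L - 1L),
                         source_row = c(rep(NA_integer_, pad), 0:(T_ - 1L)))
      fl <- structure(list(values = vals, row_provenance = prov,
                           sequence_length = L, source_shape = c(T_, F_),
                           feature_names = s$feature_names,
                           feature_kinds = s$feature_kinds, entity_id = id),
                      class = "flat_design")
    }
    fl$row_provenance$entity <- id
    fl
  })
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  prov <- do.call(rbind, lapply(parts, `[[`, "row_provenance"))
  rownames(prov) <- NULL
  ref <- collection$series[[1]]
  structure(list(values = values, row_provenance = prov, sequence_length = L,
                 source_shape = c(nrow(values), ncol(values)),
                 feature_names = ref$feature_names,
                 feature_kinds = ref$feature_kinds, entity_id = NULL),
            class = "flat_design")
}

# Inverse of window_collection for imputed values: per-entity gather + reduce.
# Cells never covered (truncated-away rows, or missing cells in uncovered
# rows) keep the source value; remaining NA cells are the caller's concern.
collapse_collection <- function(flat_imputed, collection, reducer = "mean") {
  prov <- flat_imputed$row_provenance
  out <- collection$series
  for (id in names(out)) {
    s <- out[[id]]
    rows <- which(prov$entity == id & !is.na(prov$source_row))
    vals <- flat_imputed$values[rows, , drop = FALSE]
    srow <- prov$source_row[rows] + 1L
    newv <- s$values
    if (reducer == "mean") {
      sums <- rowsum(vals, group = srow)
      cnt <- as.vector(rowsum(rep(1, length(srow)), group = srow))
      newv[sort(unique(srow)), ] <- sums / cnt
    } else {
      for (g in unique(srow)) {
        m <- vals[srow == g, , drop = FALSE]
        newv[g, ] <- if (reducer == "first") m[1L, ] else apply(m, 2, stats::median)
      }
    }
    # keep original observed values where present (passthrough happens later
    # at the pipeline level; here we only reconcile copies)
    out[[id]] <- temporal_series(newv, time_index = s$time_index,
                                 feature_names = s$feature_names,
                                 feature_kinds = s$feature_kinds, entity_id = id)
  }
  entity_collection(out, label_name = collection$label_name)
}
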