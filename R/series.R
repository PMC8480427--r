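#' Construct a temporal series
#'
#' A `temporal_series` is the basic container of the package: a `T x F` numeric
#' matrix of repeated measurements for one entity, with an ordered time index.
#' Missing cells are `NA`.
#'
#' @param values numeric matrix (or data.frame coercible to one), rows are
#'   timesteps, columns are features.
#' @param time_index optional ordered vector of timestamps or integer
#'   positions, length `nrow(values)`. Timestamps are kept for display but all
#'   internal computation uses 0-based ordinal positions.
#' @param feature_names optional character vector of feature names; defaults
#'   to the column names of `values`.
#' @param feature_kinds per-feature tag, `"continuous"` or `"categorical"`,
#'   recycled if length 1.
#' @param entity_id optional identifier of the measured entity.
#' @return an object of class `temporal_series` with fields `values`,
#'   `time_index`, `feature_names`, `feature_kinds`, `entity_id`.
#' @examples
#' ts <- temporal_series(matrix(rnorm(20), 10, 2))
#' dim(ts$values)
#' @export
temporal_series <- function(values, time_index = NULL, feature_names = NULL,
                            feature_kinds = "continuous", entity_id = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  T_ <- nrow(values); F_ <- ncol(values)
  if (T_ < 1L || F_ < 1L) stop("values must have at least one row and one column")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(F_))
  }
  if (length(feature_names) != F_) stop("feature_names length must equal ncol(values)")
  colnames(values) <- feature_names
  if (is.null(time_index)) time_index <- seq_len(T_) - 1L
  if (length(time_index) != T_) stop("time_index length must equal nrow(values)")
  if (is.unsorted(time_index, strictly = TRUE)) stop("time_index must be strictly increasing")
  feature_kinds <- rep_len(as.character(feature_kinds), F_)
  if (!all(feature_kinds %in% c("continuous", "categorical")))
    stop("feature_kinds must be 'continuous' or 'categorical'")
  structure(list(values = values, time_index = time_index,
                 feature_names = feature_names, feature_kinds = feature_kinds,
                 entity_id = entity_id),
            class = "temporal_series")
}

#' @export
print.temporal_series <- function(x, ...) {
  cat(sprintf("<temporal_series> %d timesteps x %d features", nrow(x$values), ncol(x$values)))
  if (!is.null(x$entity_id)) cat(sprintf(" [entity %s]", x$entity_id))
  nmiss <- sum(is.na(x$values))
  cat(sprintf(", %d missing cells (%.1f%%)\n", nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' Coerce to a temporal series
#' @param x matrix, data.frame or `temporal_series`.
#' @param ... passed to [temporal_series()].
#' @return a `temporal_series`.
#' @export
as_temporal_series <- function(x, ...) {
  if (inherits(x, "temporal_series")) return(x)
  temporal_series(x, ...)
}

#' Construct a multi-entity series collection
#'
#' Bundles several [temporal_series()] objects (one per entity) that share a
#' feature schema — the irregular-sampling case where entities have different
#' numbers of repeated measurements.
#'
#' @param series named list of `temporal_series` (names are entity ids), or an
#'   unnamed list whose elements carry `entity_id`s.
#' @param label_name optional feature designated as the downstream label.
#' @return an object of class `entity_collection`.
#' @export
entity_collection <- function(series, label_name = NULL) {
  if (!length(series)) stop("collection must contain at least one entity")
  series <- lapply(series, as_temporal_series)
  ids <- names(series)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(seq_along(series), function(i) {
      id <- series[[i]]$entity_id
      if (is.null(id)) as.character(i) else as.character(id)
    }, character(1))
  }
  if (anyDuplicated(ids)) stop("entity ids must be unique")
  names(series) <- ids
  ref <- series[[1]]
  for (s in series) {
    if (!identical(s$feature_names, ref$feature_names) ||
        !identical(s$feature_kinds, ref$feature_kinds))
      stop("all entities must share feature_names and feature_kinds")
  }
  if (!is.null(label_name) && !label_name %in% ref$feature_names)
    stop("label_name not among feature_names")
  structure(list(series = series, label_name = label_name),
            class = "entity_collection")
}

#' @export
print.entity_collection <- function(x, ...) {
  lens <- vapply(x$series, function(s) nrow(s$values), integer(1))
  cat(sprintf("<entity_collection> %d entities, %d features, lengths %d-%d (mean %.1f)\n",
              length(x$series), ncol(x$series[[1]]$values),
              min(lens), max(lens), mean(lens)))
  invisible(x)
}

#' Read a regular series from a wide CSV
#'
#' Wide dialect: a header row of feature names, one row per timestep, an
#' optional first column named `time`. Missing cells are empty fields or `NA`.
#'
#' @param path file path.
#' @return a `temporal_series`.
#' @export
read_series_wide <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  time_index <- NULL
  if (ncol(df) >= 2L && identical(names(df)[1], "time")) {
    time_index <- df[[1]]
    df <- df[-1]
  }
  temporal_series(as.matrix(df), time_index = time_index)
}

#' Write a regular series to a wide CSV
#' @param series a `temporal_series`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_series_wide <- function(series, path) {
  series <- as_temporal_series(series)
  df <- data.frame(time = series$time_index, series$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a multi-entity collection from a long CSV
#'
#' Long dialect: columns `entity_id`, `time`, then one column per feature.
#'
#' @param path file path.
#' @param label_name optional downstream label feature.
#' @return an `entity_collection`.
#' @export
read_collection_long <- function(path, label_name = NULL) {
  df <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  if (!all(c("entity_id", "time") %in% names(df)))
    stop("long CSV must have entity_id and time columns")
  feats <- setdiff(names(df), c("entity_id", "time"))
  parts <- split(df, df$entity_id)
  series <- lapply(parts, function(p) {
    p <- p[order(p$time), , drop = FALSE]
    temporal_series(as.matrix(p[feats]), time_index = p$time,
                    entity_id = as.character(p$entity_id[1]))
  })
  entity_collection(series, label_name = label_name)
}

#' Write a multi-entity collection to a long CSV
#' @param collection an `entity_collection`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_collection_long <- function(collection, path) {
  stopifnot(inherits(collection, "entity_collection"))
  rows <- lapply(names(collection$series), function(id) {
    s <- collection$series[[id]]
    data.frame(entity_id = id, time = s$time_index, s$values, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
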