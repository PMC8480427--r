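#' Specify a synthetic temporal dataset
#'
#' The generator draws `n_factors` latent AR(1) processes
#' `x_t = phi * x_{t-1} + eps_t` (stationary initialization) and maps them
#' through a loading matrix to `n_features` observed features plus Gaussian
#' observation noise, so the data carry both temporal autocorrelation and
#' cross-feature correlation — the two correlation axes a temporal imputer is
#' supposed to exploit. An optional label column with known feature dependence
#' supports downstream congeniality evaluation.
#'
#' @param n_timesteps series length T (regular case) — ignored when
#'   `length_range` is given.
#' @param n_features number of observed features F (label excluded).
#' @param n_entities number of entities for [generate_irregular()].
#' @param n_factors number of latent AR(1) factors k.
#' @param ar AR(1) coefficient phi in `[0, 1)`.
#' @param loadings optional `F x k` loading matrix; by default drawn once from
#'   the spec seed, entries uniform on `[-1, 1]` scaled by `1/sqrt(k)`.
#' @param noise_sd observation-noise standard deviation (> 0).
#' @param label `"none"`, `"linear"` (label = `label_coef %*% features` +
#'   `label_noise_sd` noise, appended as column `"label"`) or `"binary"`
#'   (indicator of the linear score exceeding its median, a categorical
#'   feature).
#' @param label_coef coefficients of length `n_features`; default
#'   `(1, -1, 0, 0, ...)`.
#' @param label_noise_sd label noise standard deviation (default 0.1; 0 gives
#'   a noiseless label).
#' @param length_range integer pair `c(min, max)`: per-entity lengths drawn
#'   uniformly from `min..max` (irregular case).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_timesteps = 300, n_features = 5, n_entities = 1,
                       n_factors = 2, ar = 0.8, loadings = NULL,
                       noise_sd = 0.1, label = c("none", "linear", "binary"),
                       label_coef = NULL, label_noise_sd = 0.1,
                       length_range = NULL, seed = 1) {
  label <- match.arg(label)
  if (ar < 0 || ar >= 1) stop("ar coefficient must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(length_range)) {
    length_range <- as.integer(length_range)
    if (length(length_range) != 2L || length_range[1] < 2L ||
        length_range[2] < length_range[1])
      stop("length_range must be c(min, max) with min >= 2")
  }
  if (is.null(label_coef) && label != "none")
    label_coef <- c(1, -1, rep(0, max(0, n_features - 2)))[seq_len(n_features)]
  structure(list(n_timesteps = as.integer(n_timesteps),
                 n_features = as.integer(n_features),
                 n_entities = as.integer(n_entities),
                 n_factors = as.integer(n_factors), ar = ar,
                 loadings = loadings, noise_sd = noise_sd, label = label,
                 label_coef = label_coef, label_noise_sd = label_noise_sd,
                 length_range = length_range, seed = as.integer(seed)),
            class = "synth_spec")
}

# loading matrix is a deterministic function of the spec seed so that every
# entity of a collection shares the same cross-feature structure
synth_loadings <- function(spec) {
  if (!is.null(spec$loadings)) {
    stopifnot(nrow(spec$loadings) == spec$n_features,
              ncol(spec$loadings) == spec$n_factors)
    return(spec$loadings)
  }
  set.seed(derive_seed(spec$seed, "loadings"))
  matrix(stats::runif(spec$n_features * spec$n_factors, -1, 1) / sqrt(spec$n_factors),
         spec$n_features, spec$n_factors)
}

# one latent AR(1) factor path with stationary start, innovation sd 1
ar1_path <- function(n, phi) {
  eps <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- eps[1] / sqrt(max(1 - phi^2, .Machine$double.eps))
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + eps[t]
  x
}

# core draw: T x F feature block (+ optional label column)
synth_block <- function(spec, T_, lam) {
  k <- spec$n_factors; F_ <- spec$n_features
  X <- vapply(seq_len(k), function(j) ar1_path(T_, spec$ar), numeric(T_))
  feats <- X %*% t(lam) +
    matrix(stats::rnorm(T_ * F_, sd = spec$noise_sd), T_, F_)
  colnames(feats) <- paste0("f", seq_len(F_))
  kinds <- rep("continuous", F_)
  if (spec$label != "none") {
    score <- drop(feats %*% spec$label_coef)
    lab <- if (spec$label == "linear") {
      if (spec$label_noise_sd > 0)
        score + stats::rnorm(T_, sd = spec$label_noise_sd) else score
    } else {
      as.numeric(score > stats::median(score))
    }
    feats <- cbind(feats, label = lab)
    kinds <- c(kinds, if (spec$label == "binary") "categorical" else "continuous")
  }
  list(values = feats, kinds = kinds)
}

#' Generate a complete regular temporal series
#'
#' @param spec a [synth_spec()].
#' @return a fully observed `temporal_series` (label appended as last column
#'   when the spec requests one).
#' @examples
#' ts <- generate_regular(synth_spec(n_timesteps = 50, seed = 7))
#' anyNA(ts$values)
#' @export
generate_regular <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  lam <- synth_loadings(spec)
  set.seed(derive_seed(spec$seed, "regular"))
  b <- synth_block(spec, spec$n_timesteps, lam)
  temporal_series(b$values, feature_kinds = b$kinds)
}

#' Generate a complete irregular multi-entity collection
#'
#' Per-entity independent series with entity-specific lengths drawn uniformly
#' from `spec$length_range`; all entities share the loading matrix, so
#' cross-feature structure is common while trajectories differ.
#'
#' @param spec a [synth_spec()] with `length_range` set (or `n_timesteps`
#'   reused for every entity when not).
#' @return an `entity_collection`; `label_name` is `"label"` when the spec
#'   requests a label.
#' @export
generate_irregular <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  lam <- synth_loadings(spec)
  set.seed(derive_seed(spec$seed, "lengths"))
  lens <- if (is.null(spec$length_range)) rep(spec$n_timesteps, spec$n_entities)
          else sample(spec$length_range[1]:spec$length_range[2],
                      spec$n_entities, replace = TRUE)
  series <- lapply(seq_len(spec$n_entities), function(i) {
    set.seed(derive_seed(spec$seed, paste0("entity", i)))
    b <- synth_block(spec, lens[i], lam)
    temporal_series(b$values, feature_kinds = b$kinds, entity_id = as.character(i))
  })
  names(series) <- as.character(seq_len(spec$n_entities))
  entity_collection(series,
                    label_name = if (spec$label != "none") "label" else NULL)
}

#' Write / read a synthetic spec as a YAML sidecar
#' @param spec a `synth_spec`.
#' @param path YAML file path.
#' @return `path` invisibly / the restored `synth_spec`.
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  x <- unclass(spec)
  if (!is.null(x$loadings)) x$loadings <- as.vector(x$loadings)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$loadings))
    x$loadings <- matrix(unlist(x$loadings), x$n_features, x$n_factors)
  do.call(synth_spec, x[setdiff(names(x), character())])
}
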