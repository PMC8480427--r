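#' Normalize a series feature-wise
#'
#' Per-feature min-max scaling to `[0, 1]` (default) or z-scoring, with
#' statistics computed on observed cells only. Fitted statistics can be reused
#' on held-out data. Evaluation (RMSE, downstream R-squared) happens on the
#' normalized scale; model outputs are not transformed back for scoring.
#'
#' @param series a `temporal_series` or `entity_collection`.
#' @param stats optional statistics from a previous call (reuse on new data).
#' @param method `"minmax"` or `"zscore"`.
#' @return list with `series` (scaled, same class as input) and `stats`
#'   (data.frame with per-feature `center`/`scale`).
#' @export
normalize_series <- function(series, stats = NULL, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (inherits(series, "entity_collection")) {
    if (is.null(stats)) {
      pooled <- do.call(rbind, lapply(series$series, `[[`, "values"))
      stats <- norm_stats(pooled, method)
    }
    out <- series
    out$series <- lapply(series$series, function(s) {
      s$values <- norm_apply(s$values, stats)
      s
    })
    return(list(series = out, stats = stats))
  }
  series <- as_temporal_series(series)
  if (is.null(stats)) stats <- norm_stats(series$values, method)
  series$values <- norm_apply(series$values, stats)
  list(series = series, stats = stats)
}

norm_stats <- function(values, method) {
  F_ <- ncol(values)
  center <- numeric(F_); scale <- numeric(F_)
  for (f in seq_len(F_)) {
    v <- values[, f]; v <- v[!is.na(v)]
    if (!length(v)) stop("feature with zero observed values")
    if (method == "minmax") {
      center[f] <- min(v); scale[f] <- max(v) - min(v)
    } else {
      center[f] <- mean(v); scale[f] <- stats::sd(v)
      if (is.na(scale[f])) scale[f] <- 0
    }
    if (scale[f] == 0) {
      warning(sprintf("constant feature %d scaled to 0", f))
      scale[f] <- 1   # (v - center)/1 = 0 everywhere observed
    }
  }
  data.frame(feature = colnames(values) %||% paste0("f", seq_len(F_)),
             center = center, scale = scale, method = method)
}

norm_apply <- function(values, stats) {
  sweep(sweep(values, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Invert [normalize_series()]
#' @param series scaled `temporal_series` or `entity_collection`.
#' @param stats the statistics returned by [normalize_series()].
#' @return the series on the original scale.
#' @export
denormalize_series <- function(series, stats) {
  inv <- function(values) sweep(sweep(values, 2, stats$scale, "*"), 2, stats$center, "+")
  if (inherits(series, "entity_collection")) {
    series$series <- lapply(series$series, function(s) { s$values <- inv(s$values); s })
    return(series)
  }
  series <- as_temporal_series(series)
  series$values <- inv(series$values)
  series
}

#' Hide observed cells completely at random
#'
#' Each maskable cell is hidden independently with probability `rate`,
#' emulating the missing-completely-at-random mechanism. Masking happens on
#' the source matrix before windowing, so every window copy of a cell shares
#' its missingness. When `label_protected` and a label is given, label-column
#' cells are never masked (so downstream R-squared measures feature-imputation
#' quality).
#'
#' @param series a fully observed (in maskable cells) `temporal_series` or
#'   `entity_collection`.
#' @param rate target masking fraction, strictly between 0 and 1.
#' @param seed integer seed; the mask is a deterministic function of it.
#' @param label_protected protect the label column from masking.
#' @param label label feature name (defaults to the collection's
#'   `label_name`).
#' @return list with `masked` (series with `NA`s) and `mask` (class
#'   `mcar_mask`: logical matrix/list of matrices, plus `rate`, `seed`,
#'   `label_protected`).
#' @export
apply_mcar_mask <- function(series, rate, seed = 1, label_protected = TRUE,
                            label = NULL) {
  if (!is.numeric(rate) || rate <= 0 || rate >= 1)
    stop("rate must be strictly between 0 and 1")
  if (inherits(series, "entity_collection")) {
    label <- label %||% series$label_name
    masked <- series
    masks <- list()
    for (i in seq_along(series$series)) {
      id <- names(series$series)[i]
      one <- mask_one(series$series[[i]], rate,
                      derive_seed(seed, paste0("mask", id)), label_protected, label)
      masked$series[[i]] <- one$masked
      masks[[id]] <- one$mask
    }
    mask <- structure(list(mask = masks, rate = rate, seed = seed,
                           label_protected = label_protected),
                      class = "mcar_mask")
    return(list(masked = masked, mask = mask))
  }
  one <- mask_one(as_temporal_series(series), rate, seed, label_protected, label)
  mask <- structure(list(mask = one$mask, rate = rate, seed = seed,
                         label_protected = label_protected),
                    class = "mcar_mask")
  list(masked = one$masked, mask = mask)
}

mask_one <- function(series, rate, seed, label_protected, label) {
  vals <- series$values
  maskable <- !is.na(vals)
  if (label_protected && !is.null(label) && label %in% series$feature_names)
    maskable[, match(label, series$feature_names)] <- FALSE
  set.seed(seed)
  hide <- matrix(stats::runif(length(vals)) < rate, nrow(vals), ncol(vals)) & maskable
  vals[hide] <- NA_real_
  series$values <- vals
  list(masked = series, mask = hide)
}

#' RMSE over artificially masked cells
#'
#' `sqrt(mean((imputed - truth)^2))` over the cells hidden by the mask, on
#' whatever scale the inputs are on (the evaluation protocol scores on the
#' normalized scale and does not renormalize model output).
#'
#' @param imputed,truth `temporal_series` or `entity_collection` of matching
#'   shape.
#' @param mask an `mcar_mask`.
#' @return nonnegative scalar.
#' @export
rmse_masked <- function(imputed, truth, mask) {
  stopifnot(inherits(mask, "mcar_mask"))
  if (inherits(truth, "entity_collection")) {
    se <- 0; nc <- 0
    for (id in names(truth$series)) {
      m <- mask$mask[[id]]
      d <- imputed$series[[id]]$values[m] - truth$series[[id]]$values[m]
      se <- se + sum(d^2); nc <- nc + length(d)
    }
    if (nc == 0) stop("mask hides no cells")
    return(sqrt(se / nc))
  }
  m <- mask$mask
  if (!any(m)) stop("mask hides no cells")
  d <- as_temporal_series(imputed)$values[m] - as_temporal_series(truth)$values[m]
  sqrt(mean(d^2))
}

#' Classic imputation baselines
#'
#' * `mean`: per-feature observed mean.
#' * `linear_interp`: per-feature linear interpolation along time, boundary
#'   cells filled with the nearest observed value.
#' * `spline_interp` / `cubic_interp`: natural-spline / cubic (Forsythe-
#'   Malcolm-Moler) interpolation along time, boundary cells filled with the
#'   nearest observed value.
#' * `knn`: distance-weighted average of the `k` nearest rows (Euclidean
#'   distance over jointly observed features, weights `1/d`), neighbours
#'   restricted to rows where the target feature is observed.
#'
#' @param series a partially observed `temporal_series` or
#'   `entity_collection` (interpolation runs within each entity).
#' @param method baseline name.
#' @param k neighbourhood size for `knn`.
#' @return a fully imputed series of the same class.
#' @export
baseline_impute <- function(series,
                            method = c("mean", "linear_interp", "spline_interp",
                                       "cubic_interp", "knn"),
                            k = 5) {
  method <- match.arg(method)
  if (inherits(series, "entity_collection")) {
    out <- series
    if (method == "mean") {
      pooled <- do.call(rbind, lapply(series$series, `[[`, "values"))
      mu <- colMeans(pooled, na.rm = TRUE)
      if (any(is.na(mu))) stop("feature with zero observed values")
      out$series <- lapply(series$series, function(s) {
        for (f in seq_along(mu)) s$values[is.na(s$values[, f]), f] <- mu[f]
        s
      })
    } else {
      out$series <- lapply(series$series, function(s)
        baseline_impute(s, method = method, k = k))
    }
    return(out)
  }
  series <- as_temporal_series(series)
  vals <- series$values
  T_ <- nrow(vals); F_ <- ncol(vals)
  for (f in seq_len(F_)) {
    obs <- which(!is.na(vals[, f]))
    if (!length(obs)) stop("feature with zero observed values")
    mis <- which(is.na(vals[, f]))
    if (!length(mis)) next
    vals[, f] <- switch(
      method,
      mean = { v <- vals[, f]; v[mis] <- mean(vals[obs, f]); v },
      linear_interp = interp_fill(vals[, f], obs, mis, "linear"),
      spline_interp = interp_fill(vals[, f], obs, mis, "natural"),
      cubic_interp = interp_fill(vals[, f], obs, mis, "fmm"),
      knn = vals[, f]   # handled jointly below
    )
  }
  if (method == "knn") vals <- knn_impute(series$values, k)
  series$values <- vals
  series
}

# interpolate one feature along (integer) time; boundary fill = nearest obs
interp_fill <- function(v, obs, mis, kind) {
  t <- seq_along(v)
  if (length(obs) == 1L) { v[mis] <- v[obs]; return(v) }
  inner <- mis[mis > min(obs) & mis < max(obs)]
  if (length(inner)) {
    v[inner] <- if (kind == "linear")
      stats::approx(t[obs], v[obs], xout = t[inner])$y
    else
      stats::splinefun(t[obs], v[obs], method = kind)(t[inner])
  }
  v[mis[mis < min(obs)]] <- v[min(obs)]
  v[mis[mis > max(obs)]] <- v[max(obs)]
  v
}

# distance-weighted kNN over rows; distance on jointly observed features,
# mean-normalized by the number of shared features to compare fairly
knn_impute <- function(vals, k) {
  T_ <- nrow(vals); F_ <- ncol(vals)
  out <- vals
  miss_rows <- which(rowSums(is.na(vals)) > 0)
  for (i in miss_rows) {
    for (f in which(is.na(vals[i, ]))) {
      cand <- which(!is.na(vals[, f]) & seq_len(T_) != i)
      if (!length(cand)) stop("feature with zero observed values")
      d <- vapply(cand, function(j) {
        shared <- !is.na(vals[i, ]) & !is.na(vals[j, ])
        shared[f] <- FALSE
        if (!any(shared)) return(Inf)
        sqrt(mean((vals[i, shared] - vals[j, shared])^2))
      }, numeric(1))
      ord <- order(d)[seq_len(min(k, length(cand)))]
      dd <- d[ord]
      if (any(dd == 0)) {
        out[i, f] <- mean(vals[cand[ord][dd == 0], f])
      } else if (all(!is.finite(dd))) {
        out[i, f] <- mean(vals[cand, f])
      } else {
        w <- 1 / dd[is.finite(dd)]
        out[i, f] <- sum(w * vals[cand[ord][is.finite(dd)], f]) / sum(w)
      }
    }
  }
  out
}

#' Downstream congeniality of an imputation
#'
#' Fits `label ~ other features` on the training portion of a 70:30 holdout
#' (time-ordered by default, to avoid leakage between adjacent rows) and
#' reports test-set R-squared, for each of the original and the imputed data
#' and each of a nonlinear model (gradient-boosted regression trees) and a
#' linear model (ordinary least squares). The row split is identical across
#' all four fits. A congeniality gap (imputed minus original R-squared) near
#' zero means the imputation preserved the feature-label relationships.
#'
#' @param imputed,original `temporal_series` or `entity_collection` (rows are
#'   pooled across entities, in entity order).
#' @param label label feature name.
#' @param split_ratio training fraction (default 0.7).
#' @param seed seed for the random split (only used when
#'   `time_ordered = FALSE`) and the boosted-trees fit.
#' @param time_ordered use the first `split_ratio` rows as training set.
#' @param nrounds,max_depth,eta boosted-trees hyperparameters.
#' @return data.frame with one row per model (`gbr`, `lr`): `r2_original`,
#'   `r2_imputed`, `congeniality_gap`.
#' @export
congeniality_eval <- function(imputed, original, label, split_ratio = 0.7,
                              seed = 1, time_ordered = TRUE,
                              nrounds = 100, max_depth = 3, eta = 0.1) {
  Xo <- pool_rows(original); Xi <- pool_rows(imputed)
  stopifnot(identical(dim(Xo), dim(Xi)))
  lab <- match(label, colnames(Xo))
  if (is.na(lab)) stop("label column not found")
  if (anyNA(Xo)) stop("original data must be complete")
  n <- nrow(Xo)
  if (time_ordered) {
    train <- seq_len(floor(split_ratio * n))
  } else {
    set.seed(derive_seed(seed, "split"))
    train <- sort(sample.int(n, floor(split_ratio * n)))
  }
  test <- setdiff(seq_len(n), train)
  y_tr <- Xo[train, lab]; y_te <- Xo[test, lab]
  if (stats::var(y_te) == 0) stop("degenerate label variance in test split")
  r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  fit_both <- function(X) {
    Ftr <- X[train, -lab, drop = FALSE]; Fte <- X[test, -lab, drop = FALSE]
    bst <- xgboost::xgboost(x = Ftr, y = y_tr, nrounds = nrounds,
                            max_depth = max_depth, learning_rate = eta,
                            objective = "reg:squarederror", nthreads = 1,
                            verbosity = 0, seed = derive_seed(seed, "gbr"))
    df_tr <- as.data.frame(Ftr); df_te <- as.data.frame(Fte)
    names(df_tr) <- names(df_te) <- paste0("x", seq_len(ncol(Ftr)))
    lin <- stats::lm(y ~ ., data = cbind(y = y_tr, df_tr))
    c(gbr = r2(y_te, stats::predict(bst, Fte)),
      lr = r2(y_te, stats::predict(lin, df_te)))
  }
  ro <- fit_both(Xo); ri <- fit_both(Xi)
  data.frame(model = c("gbr", "lr"), r2_original = as.numeric(ro),
             r2_imputed = as.numeric(ri),
             congeniality_gap = as.numeric(ri - ro))
}

pool_rows <- function(x) {
  if (inherits(x, "entity_collection"))
    do.call(rbind, lapply(x$series, `[[`, "values"))
  else as_temporal_series(x)$values
}

#' Run the full masking/imputation/evaluation grid
#'
#' For every (method, rate, seed) cell: mask the complete data completely at
#' random, normalize (statistics from the masked data's observed cells),
#' impute on the normalized scale, score masked-cell RMSE against the
#' normalized truth, and (when a label is present) downstream congeniality.
#'
#' @param data a complete `temporal_series` or `entity_collection`.
#' @param methods character vector from `"mean"`, `"linear_interp"`,
#'   `"spline_interp"`, `"cubic_interp"`, `"knn"`, `"tsignn"`, `"grape"`
#'   (`grape` = the non-windowed graph imputer, sequence length effectively
#'   1).
#' @param rates masking rates (default `c(0.3, 0.6)`).
#' @param seeds integer vector of seeds.
#' @param label optional label feature (protected from masking).
#' @param sequence_length window length for `"tsignn"`.
#' @param config an [imputer_config()] for the graph methods.
#' @param k neighbourhood size for `"knn"`.
#' @return data.frame with columns `method`, `rate`, `seed`, `rmse`,
#'   `r2_gbr_orig`, `r2_gbr_imp`, `r2_lr_orig`, `r2_lr_imp`.
#' @export
run_experiment <- function(data, methods = c("mean", "tsignn"),
                           rates = c(0.3, 0.6), seeds = 1,
                           label = NULL, sequence_length = 10,
                           config = imputer_config(), k = 5) {
  known <- c("mean", "linear_interp", "spline_interp", "cubic_interp", "knn",
             "tsignn", "grape")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop(sprintf("unknown method(s) %s; registered methods: %s",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  if (inherits(data, "entity_collection") && is.null(label))
    label <- data$label_name
  rows <- list()
  for (rate in rates) for (seed in seeds) {
    mk <- apply_mcar_mask(data, rate, seed = seed,
                          label_protected = !is.null(label), label = label)
    nm <- normalize_series(mk$masked)
    truth_scaled <- normalize_series(data, stats = nm$stats)$series
    for (method in methods) {
      imputed <- switch(
        method,
        tsignn = ,
        grape = {
          cfg <- config
          cfg$seed <- derive_seed(seed, paste0("fit", method))
          L <- if (method == "grape") NULL else sequence_length
          fit <- tsi_gnn(nm$series, sequence_length = L, config = cfg,
                         normalize = "none")
          imputed_series(fit)
        },
        baseline_impute(nm$series, method = method, k = k))
      rmse <- rmse_masked(imputed, truth_scaled, mk$mask)
      row <- data.frame(method = method, rate = rate, seed = seed, rmse = rmse,
                        r2_gbr_orig = NA_real_, r2_gbr_imp = NA_real_,
                        r2_lr_orig = NA_real_, r2_lr_imp = NA_real_)
      if (!is.null(label)) {
        ce <- congeniality_eval(imputed, truth_scaled, label, seed = seed)
        row$r2_gbr_orig <- ce$r2_original[ce$model == "gbr"]
        row$r2_gbr_imp <- ce$r2_imputed[ce$model == "gbr"]
        row$r2_lr_orig <- ce$r2_original[ce$model == "lr"]
        row$r2_lr_imp <- ce$r2_imputed[ce$model == "lr"]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
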