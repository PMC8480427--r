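test_that("min-max scaling maps observed ranges onto [0, 1] and inverts exactly", {
  ts <- temporal_series(matrix(c(0, 5, 10, 0.2, 0.5, 0.9), 3, 2))
  nm <- normalize_series(ts)
  expect_equal(unname(nm$series$values[2, 1]), 0.5)
  expect_equal(nm$series$values[, 2], c(0, 3 / 7, 1))
  # an already-[0,1] feature spanning the full range is unchanged
  ts01 <- temporal_series(matrix(c(0, 0.3, 1), 3, 1))
  expect_equal(normalize_series(ts01)$series$values, ts01$values)

  set.seed(2)
  tsr <- random_series(40, 4, seed = 2, missing_rate = 0.2)
  nmr <- normalize_series(tsr)
  back <- denormalize_series(nmr$series, nmr$stats)
  expect_equal(back$values, tsr$values, tolerance = 1e-12)
  # fitted stats reapply to new data
  new <- random_series(10, 4, seed = 3)
  scaled <- normalize_series(new, stats = nmr$stats)$series
  expect_equal(denormalize_series(scaled, nmr$stats)$values, new$values,
               tolerance = 1e-12)
})

test_that("constant features scale to zero with a warning", {
  ts <- temporal_series(matrix(c(3, 3, 3, 1, 2, 4), 3, 2))
  expect_warning(nm <- normalize_series(ts), "constant feature")
  expect_equal(nm$series$values[, 1], c(0, 0, 0))
})

test_that("MCAR masking is calibrated, seed-deterministic and label-protecting", {
  ts <- random_series(1000, 6, seed = 10)
  mk <- apply_mcar_mask(ts, 0.3, seed = 4, label_protected = FALSE)
  frac <- mean(mk$mask$mask)
  se <- sqrt(0.3 * 0.7 / 6000)
  expect_lt(abs(frac - 0.3), 3 * se)
  # determinism: same seed identical, different seed differs
  mk2 <- apply_mcar_mask(ts, 0.3, seed = 4, label_protected = FALSE)
  expect_identical(mk2$mask$mask, mk$mask$mask)
  mk3 <- apply_mcar_mask(ts, 0.3, seed = 5, label_protected = FALSE)
  expect_gt(sum(mk3$mask$mask != mk$mask$mask), 0)
  # near-zero rate hides (almost surely) nothing
  mk0 <- apply_mcar_mask(random_series(10, 2), 1e-12, seed = 1,
                         label_protected = FALSE)
  expect_identical(sum(mk0$mask$mask), 0L)
  expect_error(apply_mcar_mask(ts, 0), "strictly between")
  expect_error(apply_mcar_mask(ts, 1), "strictly between")
  # label protection leaves the label column fully observed
  lab <- temporal_series(matrix(runif(40), 10, 4),
                         feature_names = c("a", "b", "c", "label"))
  mkl <- apply_mcar_mask(lab, 0.5, seed = 2, label_protected = TRUE,
                         label = "label")
  expect_false(any(mkl$mask$mask[, 4]))
  expect_false(anyNA(mkl$masked$values[, 4]))
})

test_that("masked-cell RMSE matches hand arithmetic and a naive loop oracle", {
  truth <- temporal_series(matrix(c(1, 3), 2, 1))
  imp <- temporal_series(matrix(c(2, 2), 2, 1))
  mask <- structure(list(mask = matrix(TRUE, 2, 1), rate = 0.5, seed = 1,
                         label_protected = FALSE), class = "mcar_mask")
  expect_equal(rmse_masked(imp, truth, mask), 1.0)
  expect_equal(rmse_masked(truth, truth, mask), 0.0)

  set.seed(30)
  tr <- random_series(50, 4, seed = 30)
  im <- random_series(50, 4, seed = 31)
  m <- matrix(runif(200) < 0.4, 50, 4)
  mk <- structure(list(mask = m, rate = 0.4, seed = 1, label_protected = FALSE),
                  class = "mcar_mask")
  acc <- 0; nc <- 0
  for (i in 1:50) for (j in 1:4) if (m[i, j]) {
    acc <- acc + (im$values[i, j] - tr$values[i, j])^2; nc <- nc + 1
  }
  expect_equal(rmse_masked(im, tr, mk), as.numeric(sqrt(acc / nc)), tolerance = 1e-12)
  mk$mask[] <- FALSE
  expect_error(rmse_masked(im, tr, mk), "no cells")
})

test_that("baseline imputers reproduce hand-computed fills", {
  # mean: observed {2, 4} -> missing filled with 3
  ts <- temporal_series(matrix(c(2, NA, 4), 3, 1))
  expect_equal(unname(baseline_impute(ts, "mean")$values[2, 1]), 3)
  # linear interpolation between t=0 (0.0) and t=2 (1.0)
  ts2 <- temporal_series(matrix(c(0, NA, 1), 3, 1))
  expect_equal(unname(baseline_impute(ts2, "linear_interp")$values[2, 1]), 0.5)
  # boundary fill is nearest observed
  ts3 <- temporal_series(matrix(c(NA, 5, 7, NA, NA), 5, 1))
  got <- baseline_impute(ts3, "linear_interp")$values[, 1]
  expect_equal(got, c(5, 5, 7, 7, 7))
  # spline interior fill matches splinefun directly
  set.seed(9)
  v <- cumsum(rnorm(12)); v[c(4, 7)] <- NA
  ts4 <- temporal_series(matrix(v, ncol = 1))
  obs <- which(!is.na(v))
  want <- splinefun(obs, v[obs], method = "natural")(c(4, 7))
  expect_equal(baseline_impute(ts4, "spline_interp")$values[c(4, 7), 1], want)
  want_c <- splinefun(obs, v[obs], method = "fmm")(c(4, 7))
  expect_equal(baseline_impute(ts4, "cubic_interp")$values[c(4, 7), 1], want_c)
  expect_error(baseline_impute(temporal_series(matrix(NA_real_, 3, 1)), "mean"),
               "zero observed")
})

test_that("knn imputation matches a hand-weighted average on a 5-row toy", {
  vals <- rbind(c(0.0, 0.0, NA),
                c(0.1, 0.0, 1.0),
                c(0.0, 0.1, 2.0),
                c(1.0, 1.0, 3.0),
                c(0.9, 1.1, 4.0))
  ts <- temporal_series(vals)
  got <- unname(baseline_impute(ts, "knn", k = 2)$values[1, 3])
  # distances from row 1 on features 1:2 (RMS over shared dims):
  d <- apply(vals[2:5, 1:2], 1, function(r) sqrt(mean((vals[1, 1:2] - r)^2)))
  ord <- order(d)[1:2]                      # rows 2 and 3
  w <- 1 / d[ord]
  want <- sum(w * vals[2:5, 3][ord]) / sum(w)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("perfect imputation is the congeniality fixed point", {
  set.seed(17)
  X <- matrix(rnorm(600), 150, 4)
  colnames(X) <- c("f1", "f2", "f3", "label")
  X[, 4] <- X[, 1] - X[, 2] + rnorm(150, sd = 0.2)
  ts <- temporal_series(X)
  ce <- congeniality_eval(ts, ts, label = "label", seed = 1)
  expect_equal(ce$congeniality_gap, c(0, 0))
  expect_identical(ce$model, c("gbr", "lr"))
})

test_that("a noiseless linear label gives linear-model R^2 of 1 on original data", {
  set.seed(18)
  X <- matrix(rnorm(450), 150, 3)
  colnames(X) <- c("f1", "f2", "label")
  X[, 3] <- 2 * X[, 1] - 0.5 * X[, 2]
  ts <- temporal_series(X)
  ce <- congeniality_eval(ts, ts, label = "label", seed = 1)
  expect_equal(ce$r2_original[ce$model == "lr"], 1.0, tolerance = 1e-8)
})

test_that("original-data linear R^2 matches the generating model's population value", {
  # features ~iid with known variance, label = b'x + noise: R^2 = b'Sb/(b'Sb+s2)
  spec <- synth_spec(n_timesteps = 3000, n_features = 3, n_factors = 3,
                     ar = 0, loadings = diag(3), noise_sd = 1e-6,
                     label = "linear", label_coef = c(1, -1, 0.5),
                     label_noise_sd = 0.8, seed = 23)
  ts <- generate_regular(spec)
  b <- c(1, -1, 0.5)
  pop_r2 <- sum(b^2) / (sum(b^2) + 0.8^2)   # features are ~N(0,1) iid
  ce <- congeniality_eval(ts, ts, label = "label", seed = 2)
  expect_equal(ce$r2_original[ce$model == "lr"], pop_r2, tolerance = 0.05)
})

test_that("mean-baseline masked RMSE approaches the feature standard deviation", {
  # on z-scored data the mean imputer's error converges to sd = 1
  rmses <- sapply(1:3, function(s) {
    ts <- random_series(800, 3, seed = 40 + s)
    mk <- apply_mcar_mask(ts, 0.3, seed = s, label_protected = FALSE)
    nm <- normalize_series(mk$masked, method = "zscore")
    truth <- normalize_series(ts, stats = nm$stats)$series
    rmse_masked(baseline_impute(nm$series, "mean"), truth, mk$mask)
  })
  expect_equal(median(rmses), 1, tolerance = 0.05)
})

test_that("hiding more data cannot help the mean baseline", {
  diffs <- sapply(1:5, function(s) {
    ts <- random_series(300, 4, seed = 50 + s)
    r <- sapply(c(0.3, 0.6), function(rate) {
      mk <- apply_mcar_mask(ts, rate, seed = s, label_protected = FALSE)
      nm <- normalize_series(mk$masked)
      truth <- normalize_series(ts, stats = nm$stats)$series
      rmse_masked(baseline_impute(nm$series, "mean"), truth, mk$mask)
    })
    r[2] - r[1]
  })
  expect_gte(median(diffs), 0)
})

test_that("the experiment grid has one row per method x rate x seed and validates methods", {
  ts <- random_series(80, 3, seed = 60)
  res <- run_experiment(ts, methods = c("mean", "linear_interp"),
                        rates = c(0.3, 0.6), seeds = 1)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$rmse > 0))
  expect_setequal(unique(res$method), c("mean", "linear_interp"))
  expect_error(run_experiment(ts, methods = "madeup"), "registered methods")
})
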