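test_that("band-power features isolate the driving band", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)[-1]
  eeg <- eeg_recording(rbind(sin(2 * pi * 10 * t)), "e1", fs, "r")
  bf <- bandpower_features(eeg)
  # compare raw (pre-z-score) band powers via the filter bank directly
  pows <- vapply(bf$band_edges, function(b) {
    flt <- signal::butter(4, b / (fs / 2), type = "pass")
    mean(signal::filtfilt(flt, eeg$data[1, ])^2)
  }, numeric(1))
  expect_gt(pows[["alpha"]] / max(pows[c("delta", "theta", "beta")]), 10)
  expect_equal(colnames(bf$features), paste0("e1_", names(bf$band_edges)))
})

test_that("features are z-scored and shaped channels x bands", {
  eeg <- eeg_recording(matrix(rnorm(8 * 3000), 8), paste0("e", 1:8), 100, "r")
  bf <- bandpower_features(eeg)
  expect_equal(ncol(bf$features), 32)
  expect_equal(unname(colMeans(bf$features)), rep(0, 32), tolerance = 1e-8)
  expect_false(anyNA(bf$features))
  expect_error(bandpower_features(eeg, bands = list(c(40, 60))),
               class = "eegbold_invalid_argument")
})

test_that("ridge recovers a realizable target and rejects a null one", {
  set.seed(4)
  X <- matrix(rnorm(3000 * 6), 3000, 6)
  beta <- c(2, -1, 0.5, 0, 1, -2)
  y <- as.numeric(X %*% beta)
  fit <- fit_predict_linear(X[1:2000, ], y[1:2000], X[2001:3000, ])
  expect_gt(cor(fit$y_pred_test, y[2001:3000]), 0.99)

  y0 <- rnorm(6000)
  X0 <- matrix(rnorm(6000 * 6), 6000, 6)
  fit0 <- fit_predict_linear(X0[1:5000, ], y0[1:5000], X0[5001:6000, ])
  expect_lt(abs(cor(fit0$y_pred_test, y0[5001:6000])), 0.2)

  expect_error(fit_predict_linear(matrix(1, 100, 3), rnorm(100),
                                  matrix(1, 10, 3)),
               class = "eegbold_degenerate_input")
})

test_that("the linear baseline consumes the same folds as the deep model", {
  ses <- tiny_session(seed = 23, n_channels = 4, n_runs = 3,
                      volumes_per_run = 110, trials_per_run = 20)
  pairs <- align_session(ses, fs_common = 50)
  fold <- make_folds(names(pairs), 1, seed = 23)[[1]]
  cache <- new.env(parent = emptyenv())
  lf <- linear_fold(pairs, fold, feature_cache = cache)
  expect_s3_class(lf, "fold_result")
  expect_equal(lf$test_run, fold$test_run)
  expect_length(lf$y_pred, length(pairs[[fold$test_run]]$bold$values))
  expect_true(is.finite(lf$r))
  # features were cached per run, none for the held-out run beyond its own
  expect_setequal(ls(cache), names(pairs))
})
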