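#' Band-power features for the linear baseline
#'
#' Per channel and canonical band: zero-phase band-pass, squaring,
#' moving-average smoothing over `smooth_s`, log transform, z-score.
#' Default bands are delta (1-4), theta (4-8), alpha (8-13), beta
#' (13-30) Hz with 1 s smoothing.
#'
#' @param eeg an [eeg_recording()].
#' @param bands list of `c(lo, hi)` pairs in Hz (within Nyquist); `NULL`
#'   uses the canonical bands with the beta edge clipped to 0.9 Nyquist.
#' @param smooth_s moving-average length in seconds.
#' @return list with `features` (samples x (channels*bands) matrix),
#'   `band_edges`, `fs_hz`.
#' @export
bandpower_features <- function(eeg, bands = NULL, smooth_s = 1) {
  if (is.null(bands)) bands <- default_bands(eeg$fs_hz)
  check_that(inherits(eeg, "eeg_recording"), "eeg must be an eeg_recording")
  nyq <- eeg$fs_hz / 2
  for (b in bands)
    if (!(b[1] > 0 && b[1] < b[2] && b[2] < nyq))
      abort_invalid("each band must satisfy 0 < lo < hi < Nyquist")
  w <- max(1L, round(smooth_s * eeg$fs_hz))
  ma <- rep(1 / w, w)
  n <- ncol(eeg$data)
  C <- nrow(eeg$data)
  feats <- matrix(0, n, C * length(bands))
  cn <- character(C * length(bands))
  col <- 0L
  for (bi in seq_along(bands)) {
    bf <- signal::butter(4, bands[[bi]] / nyq, type = "pass")
    for (ch in seq_len(C)) {
      col <- col + 1L
      p <- signal::filtfilt(bf, eeg$data[ch, ])^2
      p <- stats::filter(p, ma, sides = 2)
      p[is.na(p)] <- mean(p, na.rm = TRUE) # moving-average edge fill
      feats[, col] <- zscore(log(as.numeric(p) + 1e-12))
      cn[col] <- paste0(eeg$channel_labels[ch], "_",
                        names(bands)[bi] %||% paste0("band", bi))
    }
  }
  colnames(feats) <- cn
  if (anyNA(feats)) abort_internal("NaN in band-power features")
  list(features = feats, band_edges = bands, fs_hz = eeg$fs_hz)
}

#' Ridge regression with inner cross-validated penalty selection
#'
#' Fits `y ~ features` with an L2 penalty chosen from `ridge_grid` by
#' 5-fold cross-validated correlation on contiguous blocks of the training
#' data (contiguous, because samples are a time series), then predicts the
#' test features. Closed-form normal-equations solve; features and target
#' are centered internally.
#'
#' @param features_train,y_train training data (rows = samples).
#' @param features_test test feature matrix.
#' @param ridge_grid penalty values (>= 2 of them).
#' @param n_inner_folds inner CV folds.
#' @return list with `y_pred_test`, `chosen_penalty`, `coef`.
#' @export
fit_predict_linear <- function(features_train, y_train, features_test,
                               ridge_grid = 10^seq(-2, 4, by = 1),
                               n_inner_folds = 5) {
  check_that(length(ridge_grid) >= 2, "need at least 2 penalties in the grid")
  check_that(nrow(features_train) == length(y_train),
             "features and target lengths differ")
  if (all(apply(features_train, 2, stats::sd) == 0))
    abort_degenerate("rank-0 features: all columns constant")

  ridge_solve <- function(X, y, lambda) {
    mx <- colMeans(X)
    my <- mean(y)
    Xc <- sweep(X, 2, mx)
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    beta <- solve(A, crossprod(Xc, y - my))
    list(beta = beta, mx = mx, my = my)
  }
  ridge_predict <- function(fit, X)
    as.numeric(sweep(X, 2, fit$mx) %*% fit$beta + fit$my)

  n <- length(y_train)
  blocks <- cut(seq_len(n), n_inner_folds, labels = FALSE)
  score <- vapply(ridge_grid, function(lam) {
    mean(vapply(seq_len(n_inner_folds), function(k) {
      tr <- blocks != k
      fit <- ridge_solve(features_train[tr, , drop = FALSE], y_train[tr], lam)
      pred <- ridge_predict(fit, features_train[!tr, , drop = FALSE])
      safe_r(pred, y_train[!tr])
    }, numeric(1)))
  }, numeric(1))
  lam <- ridge_grid[which.max(score)]
  fit <- ridge_solve(features_train, y_train, lam)
  list(y_pred_test = ridge_predict(fit, features_test),
       chosen_penalty = lam, coef = fit$beta)
}

#' Run the linear baseline on one fold
#'
#' Consumes the identical `fold_spec` and aligned pairs as the deep model
#' (the fairness condition for the comparison): band-power features per
#' run, ridge fit on the training runs, prediction on the held-out run.
#'
#' @param pairs named list mapping run id to `aligned_pair`.
#' @param fold a `fold_spec`.
#' @param bands,smooth_s,ridge_grid see [bandpower_features()] and
#'   [fit_predict_linear()].
#' @param feature_cache optional environment to reuse per-run features
#'   across folds.
#' @return a `fold_result`-shaped list tagged `model = "linear"`.
#' @export
linear_fold <- function(pairs, fold, bands = NULL, smooth_s = 1,
                        ridge_grid = 10^seq(-2, 4, by = 1),
                        feature_cache = NULL) {
  feat <- function(rn) {
    if (!is.null(feature_cache) && !is.null(feature_cache[[rn]]))
      return(feature_cache[[rn]])
    f <- bandpower_features(pairs[[rn]]$eeg, bands, smooth_s)$features
    if (!is.null(feature_cache)) feature_cache[[rn]] <- f
    f
  }
  # validation run joins the ridge training set: the penalty grid plays the
  # early-stopping role via inner CV
  train_runs <- c(fold$train_runs, fold$validation_run)
  Xtr <- do.call(rbind, lapply(train_runs, feat))
  ytr <- unlist(lapply(train_runs, function(rn) pairs[[rn]]$bold$values))
  fit <- fit_predict_linear(Xtr, ytr, feat(fold$test_run), ridge_grid)
  y_true <- pairs[[fold$test_run]]$bold$values
  structure(list(fold_id = fold$fold_id, model = "linear",
                 chosen_penalty = fit$chosen_penalty,
                 y_true = y_true, y_pred = fit$y_pred_test,
                 r = safe_r(y_true, fit$y_pred_test),
                 fs_hz = pairs[[fold$test_run]]$fs_hz,
                 test_run = fold$test_run), class = "fold_result")
}


# canonical EEG bands, beta edge clipped inside Nyquist
default_bands <- function(fs_hz) {
  nyq <- fs_hz / 2
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, min(30, 0.9 * nyq)))
}
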