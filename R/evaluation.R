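#' Sample Pearson correlation
#'
#' Standard sample coefficient; a zero-variance input yields 0 with a
#' warning rather than NA (consistent with the correlation-loss
#' convention).
#' @param a,b equal-length finite vectors (>= 2 samples).
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort_invalid("inputs must have equal length")
  check_that(length(a) >= 2, "need at least 2 samples")
  check_that(all(is.finite(a)) && all(is.finite(b)), "inputs must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance input; returning r = 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Phase-randomization surrogate
#'
#' Discrete-Fourier surrogate: amplitude spectrum preserved exactly,
#' non-DC/non-Nyquist phases replaced by seeded uniform draws with
#' Hermitian symmetry, so the output is real with the original
#' periodogram but destroyed temporal alignment.
#'
#' @param y numeric vector (length >= 4).
#' @param seed integer seed.
#' @export
phase_randomize <- function(y, seed = 1) {
  check_that(length(y) >= 4, "need at least 4 samples")
  if (!all(is.finite(y))) abort_invalid("input must be finite")
  n <- length(y)
  f <- stats::fft(y)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  phases <- with_session_seed(seed, 3L, stats::runif(half, 0, 2 * pi))
  if (half >= 1) {
    k <- 2:(half + 1)
    f[k] <- Mod(f[k]) * exp(1i * phases)
    f[n - k + 2] <- Conj(f[k])
  }
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Surrogate permutation p-value for a prediction-truth correlation
#'
#' Builds `n_surrogates` phase-randomized copies of `y_true`, recomputes
#' the correlation against each, and locates the observed correlation in
#' that null: `p = (1 + #\{null r >= observed\}) / (1 + n_surrogates)`,
#' one-sided on positive correlation with add-one correction.
#'
#' @param y_pred,y_true equal-length vectors.
#' @param n_surrogates number of surrogates (1000 at full scale).
#' @param seed integer seed.
#' @return list with `p`, `observed_r`, and the vector `null_rs`.
#' @export
permutation_pvalue <- function(y_pred, y_true, n_surrogates = 1000, seed = 1) {
  check_that(n_surrogates >= 1, "n_surrogates must be >= 1")
  obs <- pearson_r(y_pred, y_true)
  null_rs <- vapply(seq_len(n_surrogates), function(i) {
    pearson_r(y_pred, phase_randomize(y_true, seed = derive_seed(seed, i)))
  }, numeric(1))
  list(p = (1 + sum(null_rs >= obs)) / (1 + n_surrogates),
       observed_r = obs, null_rs = null_rs)
}

#' Native-rate downsampling control
#'
#' Decimates the 100 Hz prediction to the native BOLD rate by averaging
#' within each TR bin, then correlates with the native-rate truth —
#' guarding against accuracy inflated by upsampled-signal smoothness.
#'
#' @param y_pred prediction at `fs_pred` Hz.
#' @param y_true_native truth at the native rate `1/tr_s`.
#' @param fs_pred prediction sampling rate (default 100).
#' @param tr_s repetition time in seconds (default 2).
#' @export
downsample_check <- function(y_pred, y_true_native, fs_pred = 100, tr_s = 2) {
  w <- round(tr_s * fs_pred)
  n_bins <- length(y_pred) %/% w
  if (abs(n_bins - length(y_true_native)) > 1)
    abort_invalid("prediction and native truth durations differ by more than one TR")
  n_bins <- min(n_bins, length(y_true_native))
  bins <- rep(seq_len(n_bins), each = w)
  y_low <- as.numeric(tapply(y_pred[seq_len(n_bins * w)], bins, mean))
  pearson_r(y_low, y_true_native[seq_len(n_bins)])
}

#' Win/loss functional validity of a predicted series
#'
#' OLS of the prediction on an intercept plus HRF-convolved win and loss
#' event regressors; a valid reward signal carries a larger win than loss
#' coefficient.
#'
#' @param y_pred predicted series.
#' @param events event table for the same run.
#' @param fs_hz rate of `y_pred`.
#' @param offset_s time already trimmed from the run start (the
#'   hemodynamic alignment delay), so regressors share the timeline.
#' @return list with `beta_win`, `beta_loss`.
#' @export
functional_validity <- function(y_pred, events, fs_hz, offset_s = 0) {
  n <- length(y_pred)
  X <- cbind(intercept = 1,
             win = event_regressor(events, "win", fs_hz, n, offset_s),
             loss = event_regressor(events, "loss", fs_hz, n, offset_s))
  if (kappa(crossprod(X)) > 1e16)
    abort_degenerate("collinear win/loss regressors")
  beta <- stats::lm.fit(X, y_pred)$coefficients
  list(beta_win = unname(beta["win"]), beta_loss = unname(beta["loss"]))
}

#' ROI-level specificity of a predicted series
#'
#' For every ROI: the Pearson correlation with the prediction, and the
#' prediction's coefficient from an OLS of the ROI series on intercept +
#' prediction + optional nuisance regressors (the ROI-level analogue of a
#' voxelwise regression with task and motion covariates).
#'
#' @param y_pred predicted series.
#' @param roi_bolds named list mapping ROI label to an aligned series of
#'   the same length.
#' @param nuisance optional matrix of nuisance regressors (rows = samples).
#' @return data frame with columns `roi`, `r`, `glm_beta`.
#' @export
specificity_report <- function(y_pred, roi_bolds, nuisance = NULL) {
  if (anyDuplicated(names(roi_bolds))) abort_invalid("duplicate ROI labels")
  rows <- lapply(names(roi_bolds), function(lab) {
    y <- roi_bolds[[lab]]
    if (length(y) != length(y_pred))
      abort_invalid("ROI series length differs from prediction")
    X <- cbind(intercept = 1, pred = y_pred)
    if (!is.null(nuisance)) X <- cbind(X, nuisance)
    beta <- stats::lm.fit(X, y)$coefficients
    data.frame(roi = lab, r = pearson_r(y_pred, y),
               glm_beta = unname(beta["pred"]))
  })
  do.call(rbind, rows)
}

#' Paired group-level tests over folds
#'
#' Paired t statistics (df = folds - 1) for deep-learning vs linear
#' held-out correlation, target vs each control ROI correlation, and win
#' vs loss beta, with mean/SD/min/max summaries. One-sided p-values are
#' reported in the direction of the scientific claim (DL > linear,
#' target > control, win > loss).
#'
#' @param per_fold list of fold records for the deep model. Each record
#'   needs `r`; `roi_r` (named vector) and `beta_win`/`beta_loss` are used
#'   when present.
#' @param linear_per_fold matching list for the linear baseline (same
#'   fold ids, same order).
#' @return a `group_report` list: `per_fold` table, `summary`, `tests`.
#' @export
group_tests <- function(per_fold, linear_per_fold = NULL) {
  n <- length(per_fold)
  check_that(n >= 2, "need at least 2 folds")
  get_num <- function(lst, field)
    vapply(lst, function(x) as.numeric(x[[field]]), numeric(1))
  if (!is.null(linear_per_fold)) {
    if (length(linear_per_fold) != n ||
        !identical(get_num(per_fold, "fold_id"),
                   get_num(linear_per_fold, "fold_id")))
      abort_invalid("deep and linear fold tables must match fold for fold")
  }
  r_dl <- get_num(per_fold, "r")
  tab <- data.frame(fold_id = get_num(per_fold, "fold_id"), r_dl = r_dl)
  tests <- list()

  paired <- function(x, y, label) {
    d <- x - y
    if (all(d == 0))
      return(data.frame(contrast = label, t = NA_real_, df = n - 1,
                        p_two_sided = NA_real_, p_one_sided = NA_real_,
                        mean_diff = 0, note = "all differences exactly zero"))
    tt <- stats::t.test(x, y, paired = TRUE)
    t1 <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
    data.frame(contrast = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p_two_sided = tt$p.value,
               p_one_sided = t1$p.value, mean_diff = mean(d), note = "")
  }

  if (!is.null(linear_per_fold)) {
    tab$r_linear <- get_num(linear_per_fold, "r")
    tests$dl_vs_linear <- paired(tab$r_dl, tab$r_linear, "r: DL vs linear")
  }
  if (!is.null(per_fold[[1]]$roi_r)) {
    rois <- names(per_fold[[1]]$roi_r)
    roi_mat <- t(vapply(per_fold, `[[`, numeric(length(rois)), "roi_r"))
    colnames(roi_mat) <- rois
    for (roi in setdiff(rois, "VS")) {
      tab[[paste0("r_", roi)]] <- roi_mat[, roi]
      tests[[paste0("vs_", roi)]] <-
        paired(roi_mat[, "VS"], roi_mat[, roi], paste0("r: VS vs ", roi))
    }
    tab$r_VS <- roi_mat[, "VS"]
  }
  if (!is.null(per_fold[[1]]$beta_win)) {
    tab$beta_win <- get_num(per_fold, "beta_win")
    tab$beta_loss <- get_num(per_fold, "beta_loss")
    tests$win_vs_loss <- paired(tab$beta_win, tab$beta_loss,
                                "beta: win vs loss")
  }

  tests_df <- do.call(rbind, tests)
  if (!is.null(tests_df)) {
    # Bonferroni within the target-vs-control family
    fam <- grepl("^r: VS vs ", tests_df$contrast)
    tests_df$p_bonferroni <- NA_real_
    if (any(fam))
      tests_df$p_bonferroni[fam] <- pmin(1, tests_df$p_two_sided[fam] * sum(fam))
  }

  summarize <- function(x) c(mean = mean(x), sd = stats::sd(x),
                             min = min(x), max = max(x))
  summary <- list(r_dl = summarize(tab$r_dl))
  if (!is.null(tab$r_linear)) summary$r_linear <- summarize(tab$r_linear)
  if (!is.null(tab$r_downsampled)) summary$r_downsampled <- summarize(tab$r_downsampled)

  structure(list(per_fold = tab, summary = summary,
                 tests = tests_df), class = "group_report")
}
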