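#' Ablation importance of each compact-block branch
#'
#' Importance of branch b is `r_full - r_ablated(b)`: the held-out
#' correlation drop when branch b's compact-block output is zeroed and the
#' prediction recomputed. Directly measures each branch's contribution to
#' the final prediction.
#'
#' @param model a trained `model_handle`.
#' @param eval_pairs list of `aligned_pair` (held-out data).
#' @return numeric vector of length `n_branches`.
#' @export
branch_importance <- function(model, eval_pairs) {
  if (!isTRUE(model$trained)) abort_state("model has not been trained")
  if (inherits(eval_pairs, "aligned_pair")) eval_pairs <- list(eval_pairs)
  B <- model$config$n_branches
  r_with_mask <- function(mask) {
    mean(vapply(eval_pairs, function(pr) {
      safe_r(pr$bold$values, forward(model, pr$eeg$data, branch_mask = mask))
    }, numeric(1)))
  }
  r_full <- r_with_mask(NULL)
  vapply(seq_len(B), function(b) {
    mask <- rep(TRUE, B)
    mask[b] <- FALSE
    r_full - r_with_mask(mask)
  }, numeric(1))
}

#' Spatial and spectral profile of one branch
#'
#' The learned spatial weights are a backward filter; the interpretable
#' forward-model pattern is the data covariance applied to the filter
#' (`C_x w`), unit-normalized. The frequency profile is the magnitude
#' response of the branch's temporal band kernel multiplied by the
#' amplitude spectrum of the spatially filtered evaluation signal,
#' max-normalized, on the kernel's DFT grid (resolution `fs /
#' temporal_kernel`).
#'
#' @param model a trained `model_handle`.
#' @param branch_id branch index.
#' @param eval_eeg an [eeg_recording()] used as the reference data.
#' @return a `branch_profile`: `branch_id`, `spatial_pattern` (unit norm),
#'   `freq_hz`, `freq_profile` (in unit range).
#' @export
branch_profile <- function(model, branch_id, eval_eeg) {
  if (!isTRUE(model$trained)) abort_state("model has not been trained")
  B <- model$config$n_branches
  if (!(branch_id >= 1 && branch_id <= B)) abort_invalid("invalid branch id")
  w <- model$params$spat[branch_id, ]
  X <- eval_eeg$data
  Xc <- X - rowMeans(X)
  Cx <- tcrossprod(Xc) / (ncol(X) - 1)
  pattern <- as.numeric(Cx %*% w)
  pattern <- pattern / sqrt(sum(pattern^2))

  k <- model$config$temporal_kernel
  fs <- eval_eeg$fs_hz
  kern <- model$params$tband[branch_id, ]
  n_half <- k %/% 2 + 1
  kr <- Mod(stats::fft(kern))[seq_len(n_half)]
  freq <- (seq_len(n_half) - 1) * fs / k

  s <- as.numeric(w %*% X)
  amp <- segment_amplitude_spectrum(s, fs, freq)
  prof <- kr * amp
  prof <- prof / max(prof)
  structure(list(branch_id = branch_id, spatial_pattern = pattern,
                 freq_hz = freq, freq_profile = prof),
            class = "branch_profile")
}

# Welch-style mean amplitude spectrum binned onto a target frequency grid
segment_amplitude_spectrum <- function(x, fs, freq_grid, seg_s = 4) {
  seg <- min(length(x), round(seg_s * fs))
  n_seg <- max(1L, length(x) %/% seg)
  f_seg <- (seq_len(seg %/% 2 + 1) - 1) * fs / seg
  amps <- rowMeans(vapply(seq_len(n_seg), function(i) {
    z <- x[((i - 1) * seg + 1):(i * seg)]
    Mod(stats::fft(z - mean(z)))[seq_len(seg %/% 2 + 1)]
  }, numeric(seg %/% 2 + 1)))
  vapply(freq_grid, function(f0) {
    # average the fine spectrum within each coarse bin
    half_bin <- (freq_grid[2] - freq_grid[1]) / 2
    sel <- f_seg >= f0 - half_bin & f_seg < f0 + half_bin
    if (!any(sel)) amps[which.min(abs(f_seg - f0))] else mean(amps[sel])
  }, numeric(1))
}

#' Rank-averaged profiles of the most influential branches
#'
#' Within each fold, branches are ranked by ablation importance; profiles
#' are then averaged across folds by rank (best with best, and so on).
#' Spatial patterns are sign-ambiguous, so each fold's pattern is flipped
#' to the orientation of the across-fold majority before averaging.
#'
#' @param fold_models list of trained `model_handle`s (one per fold).
#' @param eval_pairs list (parallel to `fold_models`) of the held-out
#'   `aligned_pair`(s) for each fold.
#' @param k how many top branches to report (default 3).
#' @return list of `k` records: `rank`, `spatial_pattern`, `freq_hz`,
#'   `freq_profile`, `mean_importance`.
#' @export
top_branches_report <- function(fold_models, eval_pairs, k = 3) {
  n_fold <- length(fold_models)
  check_that(n_fold >= 1, "need at least one fold model")
  B <- fold_models[[1]]$config$n_branches
  if (k > B) abort_invalid("k exceeds the number of branches")

  per_fold <- lapply(seq_len(n_fold), function(i) {
    prs <- eval_pairs[[i]]
    if (inherits(prs, "aligned_pair")) prs <- list(prs)
    imp <- branch_importance(fold_models[[i]], prs)
    ranked <- order(imp, decreasing = TRUE)[seq_len(k)]
    list(importance = imp[ranked],
         profiles = lapply(ranked, function(b)
           branch_profile(fold_models[[i]], b, prs[[1]]$eeg)))
  })

  lapply(seq_len(k), function(rk) {
    pats <- lapply(per_fold, function(pf) pf$profiles[[rk]]$spatial_pattern)
    ref <- pats[[1]]
    signs <- vapply(pats, function(p) sign(sum(p * ref) + 1e-12), numeric(1))
    if (sum(signs) < 0) signs <- -signs # majority orientation
    pat <- Reduce(`+`, Map(`*`, pats, signs)) / n_fold
    pat <- pat / sqrt(sum(pat^2))
    profs <- vapply(per_fold, function(pf) pf$profiles[[rk]]$freq_profile,
                    numeric(length(per_fold[[1]]$profiles[[rk]]$freq_profile)))
    prof <- rowMeans(matrix(profs, ncol = n_fold))
    list(rank = rk, spatial_pattern = pat,
         freq_hz = per_fold[[1]]$profiles[[rk]]$freq_hz,
         freq_profile = prof / max(prof),
         mean_importance = mean(vapply(per_fold, function(pf)
           pf$importance[rk], numeric(1))))
  })
}
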