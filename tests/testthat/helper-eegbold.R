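# small fixtures shared across test files; everything is generated in code

tiny_model_cfg <- function(dropout = 0) {
  model_config(n_channels = 4, n_branches = 2, temporal_kernel = 7,
               encoder_channels = 8, pool_stride = 2, dropout_rate = dropout,
               decoder_channel_reduction = 4)
}

tiny_session <- function(seed = 1, n_channels = 8, n_runs = 3,
                         volumes_per_run = 110, trials_per_run = 20,
                         bold_noise_sd = 1, ...) {
  simulate_session(synthetic_config(
    n_channels = n_channels, n_runs = n_runs,
    trials_per_run = trials_per_run, trial_duration_s = 10,
    volumes_per_run = volumes_per_run,
    sources = default_sources(n_channels),
    bold_noise_sd = bold_noise_sd, seed = seed, ...))
}

align_session <- function(ses, fs_common = 50, delay_s = 6) {
  pairs <- list()
  for (i in seq_along(ses$runs)) {
    id <- ses$runs[[i]]$run_id
    pairs[[id]] <- align_pair(ses$runs[[i]], ses$bolds$VS[[i]],
                              fs_common = fs_common, delay_s = delay_s)
  }
  pairs
}

# the reduced-profile recovery experiment: one 20-minute four-run session
# per seed, one fold, the desk-scale model and optimizer. Memoized so the
# interpretability checks can reuse the trained models.
.recovery_cache <- new.env(parent = emptyenv())

recovery_fold <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  ses <- simulate_session(synthetic_config(
    n_channels = 16, n_runs = 4, trials_per_run = 30, trial_duration_s = 10,
    volumes_per_run = 150, sources = default_sources(16), seed = seed))
  pairs <- align_session(ses, fs_common = 50)
  fold <- make_folds(names(pairs), 1, seed = seed)[[1]]
  fr <- train_fold(pairs, fold, desk_scale_model_config(16),
                   desk_scale_train_config(seed = seed))
  out <- list(session = ses, pairs = pairs, fold = fold, result = fr)
  .recovery_cache[[key]] <- out
  out
}
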