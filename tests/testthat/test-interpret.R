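test_that("branch profiles require training and reduce to filter weights on white data", {
  m <- build_model(tiny_model_cfg(), seed = 2)
  eeg <- eeg_recording(matrix(rnorm(4 * 20000), 4), paste0("e", 1:4), 100, "r")
  expect_error(branch_profile(m, 1, eeg), class = "eegbold_invalid_state")
  m$trained <- TRUE
  bp <- branch_profile(m, 1, eeg)
  w <- m$params$spat[1, ]
  cs <- abs(sum(bp$spatial_pattern * w / sqrt(sum(w^2))))
  expect_gt(cs, 0.95) # identity covariance: pattern is the filter
  expect_equal(sqrt(sum(bp$spatial_pattern^2)), 1, tolerance = 1e-9)
  expect_true(all(bp$freq_profile >= 0 & bp$freq_profile <= 1))
  expect_equal(max(bp$freq_profile), 1)
  expect_equal(diff(bp$freq_hz)[1], 100 / 7, tolerance = 1e-9)
  expect_error(branch_profile(m, 99, eeg), class = "eegbold_invalid_argument")
  expect_identical(bp, branch_profile(m, 1, eeg))
})

test_that("ablation importance singles out the coupled branch", {
  rec <- recovery_fold(1)
  fr <- rec$result
  test_pair <- rec$pairs[[rec$fold$test_run]]
  imp <- branch_importance(fr$model, test_pair)
  expect_length(imp, 4)
  top <- which.max(imp)
  expect_gte(imp[top], 5 * max(median(imp[-top]), 1e-3))
  # ablating every branch removes the signal path entirely
  dead <- forward(fr$model, test_pair$eeg$data,
                  branch_mask = rep(FALSE, 4))
  expect_lt(sd(dead) / sd(fr$y_pred), 0.3)
})

test_that("rank-averaged reports align pattern signs across folds", {
  rec <- recovery_fold(1)
  fr <- rec$result
  pair <- rec$pairs[[rec$fold$test_run]]
  rep1 <- top_branches_report(list(fr$model), list(pair), k = 3)
  expect_length(rep1, 3)
  # single fold: the report is that fold's top-k profiles
  imp <- branch_importance(fr$model, pair)
  top <- order(imp, decreasing = TRUE)[1]
  bp <- branch_profile(fr$model, top, pair$eeg)
  expect_equal(abs(sum(rep1[[1]]$spatial_pattern * bp$spatial_pattern)), 1,
               tolerance = 1e-9)
  # a sign-flipped duplicate fold leaves the average unchanged
  flipped <- build_model(fr$model$config, seed = 1)
  flipped$params <- fr$model$params
  flipped$buffers <- fr$model$buffers
  flipped$trained <- TRUE
  flipped$params$spat <- -flipped$params$spat
  rep2 <- top_branches_report(list(fr$model, flipped), list(pair, pair), k = 2)
  expect_equal(abs(sum(rep2[[1]]$spatial_pattern * rep1[[1]]$spatial_pattern)),
               1, tolerance = 1e-6)
  expect_error(top_branches_report(list(fr$model), list(pair), k = 99),
               class = "eegbold_invalid_argument")
})

test_that("with two planted sources the top branch tracks the coupled one", {
  srcs <- default_sources(16, n_sources = 2)
  ses <- simulate_session(synthetic_config(
    n_channels = 16, n_runs = 4, trials_per_run = 30, trial_duration_s = 10,
    volumes_per_run = 150, sources = srcs, seed = 1))
  pairs <- list()
  for (i in 1:4) pairs[[ses$runs[[i]]$run_id]] <-
    align_pair(ses$runs[[i]], ses$bolds$VS[[i]], fs_common = 50)
  fold <- make_folds(names(pairs), 1, seed = 1)[[1]]
  fr <- train_fold(pairs, fold, desk_scale_model_config(16),
                   desk_scale_train_config(seed = 1, max_epochs = 60))
  pair <- pairs[[fold$test_run]]
  imp <- branch_importance(fr$model, pair)
  bp <- branch_profile(fr$model, which.max(imp), pair$eeg)
  cos1 <- abs(sum(bp$spatial_pattern * srcs[[1]]$spatial_pattern))
  cos2 <- abs(sum(bp$spatial_pattern * srcs[[2]]$spatial_pattern))
  expect_gt(cos1, cos2)
  f_peak <- bp$freq_hz[which.max(bp$freq_profile)]
  expect_gt(abs(f_peak - 6), abs(f_peak - 10)) # nearer 10 Hz than 6 Hz
})
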