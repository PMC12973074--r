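test_that("the composite loss matches hand-computed values", {
  expect_equal(compute_loss(c(0, 1, 0, -1), c(0, 1, 0, -1)), -0.1,
               tolerance = 1e-9)
  expect_equal(compute_loss(c(1, 2, 3, 4), c(4, 3, 2, 1)), 4.6,
               tolerance = 1e-9)
  lc <- loss_config()
  expect_equal(lc$weight_mse, 0.9)
  expect_equal(lc$weight_corr, 0.1)
  y <- rnorm(50)
  expect_equal(compute_loss(y, y), -0.1, tolerance = 1e-9)
  expect_error(compute_loss(1:4, 1:5), class = "eegbold_invalid_argument")
})

test_that("the loss gradient matches finite differences", {
  set.seed(2)
  L <- 20; N <- 2
  Y <- matrix(rnorm(L * N), L, N)
  P <- matrix(rnorm(L * N), L, N)
  lc <- loss_config()
  g <- eegbold:::loss_grad(Y, P, lc)
  for (idx in sample(L * N, 6)) {
    eps <- 1e-6
    Pp <- P; Pp[idx] <- Pp[idx] + eps
    Pm <- P; Pm[idx] <- Pm[idx] - eps
    num <- (compute_loss(Y, Pp, lc) - compute_loss(Y, Pm, lc)) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-6)
  }
})

test_that("folds partition runs with disjoint roles and seeded draws", {
  runs <- paste0("run", 1:20)
  folds <- make_folds(runs, 10, seed = 3)
  expect_length(folds, 10)
  test_runs <- vapply(folds, `[[`, character(1), "test_run")
  expect_equal(anyDuplicated(test_runs), 0L)
  for (f in folds) {
    expect_length(f$train_runs, 18)
    expect_equal(sort(c(f$test_run, f$validation_run, f$train_runs)),
                 sort(runs))
  }
  expect_identical(make_folds(runs, 10, seed = 3), folds)
  expect_error(make_folds(paste0("r", 1:2), 1),
               class = "eegbold_invalid_argument")
  expect_error(make_folds(runs, 21), class = "eegbold_invalid_argument")
})

test_that("the early-stopping rule implements the 15-epoch criterion", {
  # monotone improvement never stops
  h <- data.frame(train = seq(2, 1, length.out = 40),
                  val = seq(2, 1, length.out = 40))
  expect_false(early_stop_check(h, 15))
  # validation rises for exactly 15 epochs while training falls
  h2 <- data.frame(train = seq(2, 1, length.out = 16),
                   val = c(1, 1 + cumsum(rep(0.01, 15))))
  expect_true(early_stop_check(h2, 15))
  # a single improvement inside the window resets the counter
  h3 <- h2
  h3$val[15] <- 0.5
  expect_false(early_stop_check(h3, 15))
})

test_that("training reduces the loss and reproduces bit-for-bit", {
  ses <- tiny_session(seed = 13, n_channels = 4, n_runs = 3,
                      volumes_per_run = 110, trials_per_run = 20)
  pairs <- align_session(ses, fs_common = 50)
  fold <- make_folds(names(pairs), 1, seed = 13)[[1]]
  mcfg <- model_config(n_channels = 4, n_branches = 2, temporal_kernel = 25,
                       encoder_channels = 8, pool_stride = 4)
  tcfg <- train_config(learning_rate = 3e-3, batch_size = 4,
                       scheduler_t_max_epochs = 10,
                       early_stop_patience_epochs = 9, max_epochs = 10,
                       windows_per_epoch = 8, window_s = 30,
                       compact_lr_mult = 0.05, seed = 21)
  fr <- train_fold(pairs, fold, mcfg, tcfg)
  expect_lte(nrow(fr$history), 10)
  expect_true(fr$stop_reason %in% c("early_stop", "max_epochs"))
  expect_lt(mean(tail(fr$history$train, 3)), mean(head(fr$history$train, 2)))
  expect_length(fr$y_pred, length(fr$y_true))
  fr2 <- train_fold(pairs, fold, mcfg, tcfg)
  expect_identical(fr$y_pred, fr2$y_pred)
  expect_identical(fr$history, fr2$history)
})

test_that("training on phase-randomized targets stays inside the null band", {
  ses <- tiny_session(seed = 17, n_channels = 4, n_runs = 3,
                      volumes_per_run = 110, trials_per_run = 20)
  pairs <- align_session(ses, fs_common = 50)
  # replace every target with an independent phase-randomized surrogate
  for (id in names(pairs)) {
    pairs[[id]]$bold$values <- phase_randomize(pairs[[id]]$bold$values,
                                               seed = match(id, names(pairs)))
  }
  fold <- make_folds(names(pairs), 1, seed = 17)[[1]]
  mcfg <- model_config(n_channels = 4, n_branches = 2, temporal_kernel = 25,
                       encoder_channels = 8, pool_stride = 4)
  tcfg <- train_config(learning_rate = 3e-3, batch_size = 4,
                       scheduler_t_max_epochs = 8,
                       early_stop_patience_epochs = 7, max_epochs = 8,
                       windows_per_epoch = 8, window_s = 30,
                       compact_lr_mult = 0.05, seed = 5)
  fr <- train_fold(pairs, fold, mcfg, tcfg)
  pv <- permutation_pvalue(fr$y_pred, fr$y_true, n_surrogates = 200, seed = 31)
  band <- quantile(pv$null_rs, c(0.025, 0.975))
  expect_gte(pv$observed_r, band[[1]])
  expect_lte(pv$observed_r, band[[2]])
})
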