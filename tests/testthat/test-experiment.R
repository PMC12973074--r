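micro_cfg <- function(seed = 1, output_dir = NULL) {
  experiment_config(
    synthetic = synthetic_config(
      n_channels = 6, n_runs = 3, trials_per_run = 16, trial_duration_s = 10,
      volumes_per_run = 90, sources = default_sources(6),
      seed = derive_seed(seed, 1L)),
    model = model_config(n_channels = 6, n_branches = 2, temporal_kernel = 25,
                         encoder_channels = 8, pool_stride = 4),
    train = train_config(learning_rate = 3e-3, batch_size = 4,
                         scheduler_t_max_epochs = 6,
                         early_stop_patience_epochs = 5, max_epochs = 6,
                         windows_per_epoch = 8, window_s = 30,
                         compact_lr_mult = 0.05, seed = seed),
    n_folds = 2, fs_common = 50,
    evaluation = list(n_surrogates = 60, alpha = 0.05,
                      rois = c("VC", "PMC", "STN")),
    interpret = list(k_top = 2),
    output_dir = output_dir, global_seed = seed)
}

test_that("config validation flags blocking problems", {
  expect_length(validate_config(micro_cfg()), 1) # surrogate-count warning only
  bad <- micro_cfg()
  bad$n_folds <- 7
  expect_true(any(grepl("n_folds", validate_config(bad))))
  bad2 <- micro_cfg()
  bad2$train$window_s <- 1e4
  f <- validate_config(bad2)
  expect_true(any(startsWith(f, "error") & grepl("window", f)))
  expect_error(model_config(dropout_rate = 1),
               class = "eegbold_invalid_argument")
  expect_error(experiment_config(n_folds = 99),
               class = "eegbold_invalid_argument")
})

test_that("the experiment driver runs end to end and reproduces itself", {
  out <- file.path(tempdir(), "exp-bundle")
  res <- run_experiment(micro_cfg(seed = 3, output_dir = out), verbose = FALSE)
  expect_s3_class(res$report, "group_report")
  expect_equal(nrow(res$report$per_fold), 2)
  expect_true(all(c("r_dl", "r_linear", "beta_win", "permutation_p",
                    "r_downsampled") %in% names(res$report$per_fold)))
  expect_equal(unique(res$report$tests$df), 1)
  expect_length(res$interpret, 2)
  expect_true(all(file.exists(file.path(
    out, c("config.json", "per_fold.tsv", "tests.tsv", "summary.json",
           "interpret.json", "fold01_prediction.tsv")))))
  res2 <- run_experiment(micro_cfg(seed = 3), verbose = FALSE)
  expect_equal(res$report$per_fold, res2$report$per_fold, tolerance = 1e-12)
})

test_that("the shipped YAML profile loads into a valid configuration", {
  path <- system.file("config", "desk_scale.yaml", package = "eegbold")
  cfg <- experiment_config_from_yaml(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$model$n_branches, 4)
  expect_equal(cfg$train$learning_rate, 3e-3)
  expect_equal(cfg$synthetic$n_runs, 12)
  expect_equal(cfg$n_folds, 10)
  expect_length(validate_config(cfg), 0)
  bad <- tempfile(fileext = ".yaml")
  writeLines("model: {dropout_rate: 1.5", bad)
  expect_error(experiment_config_from_yaml(bad),
               class = "eegbold_invalid_argument")
})
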