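#!/usr/bin/env Rscript
# Stage 2: cross-validated training of the deep translator and the ridge
# band-power baseline on identical run-level folds.
#
# Runs are aligned at 50 Hz with the 6 s hemodynamic shift; each of the 10
# folds holds out one run for testing and one for early-stopping
# validation. Writes per-fold checkpoints, predictions and a summary table.

library(eegbold)

seed <- as.integer(Sys.getenv("EEGBOLD_SEED", "1"))
cfg <- desk_scale_experiment_config(global_seed = seed)
ses <- read_session("results/session")

pairs <- list()
for (i in seq_along(ses$runs)) {
  id <- ses$runs[[i]]$run_id
  pairs[[id]] <- align_pair(ses$runs[[i]], ses$bolds$VS[[i]],
                            fs_common = cfg$fs_common, delay_s = 6)
}
folds <- make_folds(names(pairs), cfg$n_folds, seed = derive_seed(seed, 2L))

dir.create("results/folds", showWarnings = FALSE, recursive = TRUE)
cache <- new.env()
rows <- NULL
for (fold in folds) {
  message(sprintf("fold %d: test %s", fold$fold_id, fold$test_run))
  fr <- train_fold(pairs, fold, cfg$model, cfg$train, cfg$loss)
  lf <- linear_fold(pairs, fold, feature_cache = cache)
  save_model(fr$model, sprintf("results/folds/fold%02d_model.rds", fold$fold_id))
  write.table(
    data.frame(time = (seq_along(fr$y_true) - 1) / cfg$fs_common,
               y_true = fr$y_true, y_pred_dl = fr$y_pred,
               y_pred_linear = lf$y_pred),
    sprintf("results/folds/fold%02d_prediction.tsv", fold$fold_id),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- rbind(rows, data.frame(fold_id = fold$fold_id,
                                 test_run = fold$test_run,
                                 r_dl = fr$r, r_linear = lf$r,
                                 stop_reason = fr$stop_reason))
}
saveRDS(list(folds = folds, fs_common = cfg$fs_common), "results/folds/folds.rds")
write.table(rows, "results/fold_performance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("mean held-out r: DL %.3f, linear %.3f",
                mean(rows$r_dl), mean(rows$r_linear)))
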