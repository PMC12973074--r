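#!/usr/bin/env Rscript
# Stage 3: statistical validation of the per-fold predictions.
#
# Per fold: phase-randomization permutation p for the held-out correlation,
# the native-rate downsampling control, control-ROI specificity, and the
# win/loss functional-validity betas. Group level: paired t-tests (DL vs
# linear, target vs each control, win vs loss beta).

library(eegbold)

seed <- as.integer(Sys.getenv("EEGBOLD_SEED", "1"))
cfg <- desk_scale_experiment_config(global_seed = seed)
ses <- read_session("results/session")
meta <- readRDS("results/folds/folds.rds")
fs <- meta$fs_common
perf <- read.delim("results/fold_performance.tsv")

run_ids <- vapply(ses$runs, function(r) r$run_id, character(1))
dl <- list(); li <- list()
for (k in seq_along(meta$folds)) {
  fold <- meta$folds[[k]]
  pred <- read.delim(sprintf("results/folds/fold%02d_prediction.tsv", k))
  idx <- match(fold$test_run, run_ids)
  ev <- ses$events[ses$events$run_id == fold$test_run, ]
  pv <- permutation_pvalue(pred$y_pred_dl, pred$y_true,
                           n_surrogates = cfg$evaluation$n_surrogates,
                           seed = derive_seed(seed, 100L + k))
  native <- ses$bolds$VS[[idx]]
  skip <- round(6 * native$fs_hz)
  r_low <- downsample_check(pred$y_pred_dl,
                            native$values[(skip + 1):length(native$values)],
                            fs_pred = fs, tr_s = 1 / native$fs_hz)
  fv <- functional_validity(pred$y_pred_dl, ev, fs, offset_s = 6)
  rois <- c(list(VS = pred$y_true),
            setNames(lapply(cfg$evaluation$rois, function(roi) {
              b <- ses$bolds[[roi]][[idx]]
              t_nat <- (seq_along(b$values) - 1) / b$fs_hz
              y <- spline(t_nat, b$values,
                          xout = seq(0, max(t_nat), by = 1 / fs))$y
              y <- y[(round(6 * fs) + 1):length(y)]
              y[seq_len(nrow(pred))]
            }), cfg$evaluation$rois))
  spec <- specificity_report(pred$y_pred_dl, rois)
  dl[[k]] <- list(fold_id = k, r = perf$r_dl[k], permutation_p = pv$p,
                  r_downsampled = r_low, beta_win = fv$beta_win,
                  beta_loss = fv$beta_loss,
                  roi_r = setNames(spec$r, spec$roi))
  li[[k]] <- list(fold_id = k, r = perf$r_linear[k])
}

report <- group_tests(dl, li)
perm_p <- vapply(dl, function(x) x$permutation_p, numeric(1))
report$per_fold$permutation_p <- perm_p
report$per_fold$r_downsampled <- vapply(dl, function(x) x$r_downsampled,
                                        numeric(1))
write.table(report$per_fold, "results/per_fold_statistics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report$tests, "results/group_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- sum(perm_p < cfg$evaluation$alpha)
message(sprintf("%d of %d folds beat the phase-randomization null at alpha %.2f",
                sig, nrow(report$per_fold), cfg$evaluation$alpha))
print(report$tests[, c("contrast", "t", "df", "p_one_sided")])
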