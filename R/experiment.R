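#' End-to-end experiment configuration
#'
#' Bundles all stage configurations plus evaluation and interpretation
#' settings. One `global_seed` derives every stage seed through
#' [derive_seed()]'s counter scheme, so a config + seed pair reproduces the
#' whole experiment.
#'
#' @param synthetic a [synthetic_config()], or a path to a session
#'   container readable by [read_session()].
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param loss a [loss_config()].
#' @param n_folds cross-validation folds (must not exceed the number of
#'   runs).
#' @param fs_common common analysis rate in Hz passed to [align_pair()].
#' @param evaluation list: `n_surrogates` (phase-randomization draws),
#'   `alpha` (nominal level), `rois` (control ROI labels).
#' @param interpret list: `k_top` (branches reported).
#' @param output_dir where [run_experiment()] writes its bundle (NULL =
#'   nothing written).
#' @param global_seed integer master seed.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              model = model_config(),
                              train = train_config(),
                              loss = loss_config(),
                              n_folds = 4, fs_common = 100,
                              evaluation = list(n_surrogates = 1000,
                                                alpha = 0.05,
                                                rois = c("VC", "PMC", "STN")),
                              interpret = list(k_top = 3),
                              output_dir = NULL, global_seed = 1) {
  cfg <- structure(list(synthetic = synthetic, model = model, train = train,
                        loss = loss, n_folds = n_folds, fs_common = fs_common,
                        evaluation = evaluation, interpret = interpret,
                        output_dir = output_dir, global_seed = global_seed),
                   class = "experiment_config")
  findings <- validate_config(cfg)
  errs <- findings[startsWith(findings, "error")]
  if (length(errs)) abort_invalid(paste(errs, collapse = "; "))
  cfg
}

#' The desk-scale experiment configuration
#'
#' The CPU-scale profile exercised by the shipped analysis scripts: a
#' 16-channel session of twelve 5-minute runs with the default
#' nonlinear power coupling, the reduced model (4 branches, encoder 32),
#' 50 Hz analysis rate, 10 folds, and 200 surrogates.
#'
#' @param global_seed master seed.
#' @param n_folds folds (default 10).
#' @param n_runs,volumes_per_run,trials_per_run session geometry.
#' @param max_epochs per-fold epoch budget.
#' @export
desk_scale_experiment_config <- function(global_seed = 1, n_folds = 10,
                                         n_runs = 12, volumes_per_run = 150,
                                         trials_per_run = 30,
                                         max_epochs = 40) {
  experiment_config(
    synthetic = synthetic_config(
      n_channels = 16, n_runs = n_runs, trials_per_run = trials_per_run,
      trial_duration_s = 10, volumes_per_run = volumes_per_run,
      sources = default_sources(16), seed = derive_seed(global_seed, 1L)),
    model = desk_scale_model_config(16),
    train = desk_scale_train_config(seed = global_seed,
                                    max_epochs = max_epochs),
    n_folds = n_folds, fs_common = 50,
    evaluation = list(n_surrogates = 200, alpha = 0.05,
                      rois = c("VC", "PMC", "STN")),
    interpret = list(k_top = 3),
    global_seed = global_seed)
}

#' Validate an experiment configuration
#'
#' Returns a character vector of findings, each prefixed `error:`
#' (blocking) or `warning:`; an empty vector means the config is runnable.
#'
#' @param cfg an [experiment_config()] (or plain list with its fields).
#' @export
validate_config <- function(cfg) {
  f <- character(0)
  syn <- cfg$synthetic
  if (inherits(syn, "synthetic_config")) {
    ok <- tryCatch({ validate_synthetic_config(syn); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) f <- c(f, paste0("error: synthetic: ", ok))
    n_runs <- syn$n_runs
    run_s <- syn$volumes_per_run * syn$tr_s
  } else if (is.character(syn)) {
    if (!file.exists(file.path(syn, "meta.json")))
      f <- c(f, "error: synthetic: no session container at the given path")
    n_runs <- NA
    run_s <- NA
  } else {
    f <- c(f, "error: synthetic must be a synthetic_config or a path")
    n_runs <- NA; run_s <- NA
  }
  ok <- tryCatch({ validate_model_config(cfg$model); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) f <- c(f, paste0("error: model: ", ok))

  if (!is.na(n_runs) && cfg$n_folds > n_runs)
    f <- c(f, "error: n_folds exceeds the number of runs")
  if (!is.na(n_runs) && n_runs < 3)
    f <- c(f, "error: need at least 3 runs (train/validation/test)")
  if (!is.na(run_s) && cfg$train$window_s > run_s)
    f <- c(f, "error: training window longer than a run")
  L <- cfg$train$window_s * cfg$fs_common
  if (L < cfg$model$pool_stride^cfg$model$n_encoder_blocks)
    f <- c(f, "error: window too short for the encoder's pooling footprint")
  if (inherits(syn, "synthetic_config") && cfg$fs_common > syn$fs_hz)
    f <- c(f, "error: fs_common exceeds the EEG sampling rate")
  if (cfg$evaluation$n_surrogates < 100)
    f <- c(f, "warning: fewer than 100 surrogates gives a coarse p-value grid")
  f
}

# interpolate a native-rate ROI series onto the aligned prediction timeline
align_roi_values <- function(bold, n_out, fs_common, delay_s) {
  t_nat <- (seq_along(bold$values) - 1) / bold$fs_hz
  t_out <- seq(0, t_nat[length(t_nat)], by = 1 / fs_common)
  y <- stats::spline(t_nat, bold$values, xout = t_out)$y
  d <- round(delay_s * fs_common)
  y <- y[(d + 1):length(y)]
  if (length(y) < n_out) abort_internal("ROI series shorter than prediction")
  y[seq_len(n_out)]
}

#' Run the full experiment
#'
#' Generates (or loads) the session, aligns every run at the common rate
#' with the hemodynamic shift, builds run-level folds, trains the deep
#' model and the ridge band-power baseline on identical folds, evaluates
#' each fold (held-out r, phase-randomization p, native-rate downsampling
#' control, control-ROI specificity, win/loss functional validity), runs
#' the paired group tests, extracts the rank-averaged top-branch profiles,
#' and optionally writes the whole bundle to `cfg$output_dir`.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return list: `report` (a `group_report`), `dl_folds`, `linear_folds`
#'   (per-fold records), `interpret` (top-branch profiles), `oracle_r`
#'   (per-fold noise ceiling), `config` echo.
#' @export
run_experiment <- function(cfg, verbose = TRUE) {
  findings <- validate_config(cfg)
  errs <- findings[startsWith(findings, "error")]
  if (length(errs)) abort_invalid(paste(errs, collapse = "; "))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, fold_id, expr) {
    tryCatch(expr, error = function(e) {
      abort_eegbold(sprintf("stage '%s'%s failed: %s", name,
                            if (is.na(fold_id)) "" else paste0(" (fold ", fold_id, ")"),
                            conditionMessage(e)), "stage_failure")
    })
  }

  say("stage: data")
  session <- stage("data", NA, {
    if (is.character(cfg$synthetic)) read_session(cfg$synthetic)
    else simulate_session(cfg$synthetic)
  })
  events <- session$events
  delay_s <- if (inherits(cfg$synthetic, "synthetic_config"))
    cfg$synthetic$hrf_delay_s else 6

  say("stage: align (%d runs at %g Hz)", length(session$runs), cfg$fs_common)
  pairs <- stage("align", NA, {
    out <- list()
    for (i in seq_along(session$runs)) {
      run <- session$runs[[i]]
      out[[run$run_id]] <- align_pair(run, session$bolds$VS[[i]],
                                      fs_common = cfg$fs_common,
                                      delay_s = delay_s)
    }
    out
  })

  folds <- make_folds(names(pairs), cfg$n_folds,
                      seed = derive_seed(cfg$global_seed, 2L))
  feature_cache <- new.env(parent = emptyenv())
  dl_folds <- list()
  linear_folds <- list()
  oracle_r <- numeric(0)

  for (fold in folds) {
    say("fold %d/%d: train DL (test %s)", fold$fold_id, length(folds),
        fold$test_run)
    fr <- stage("train", fold$fold_id,
                train_fold(pairs, fold, cfg$model, cfg$train, cfg$loss))
    lf <- stage("linear", fold$fold_id,
                linear_fold(pairs, fold, feature_cache = feature_cache))

    ev_fold <- stage("evaluate", fold$fold_id, {
      run_idx <- match(fold$test_run,
                       vapply(session$runs, `[[`, character(1), "run_id"))
      pv <- permutation_pvalue(fr$y_pred, fr$y_true,
                               n_surrogates = cfg$evaluation$n_surrogates,
                               seed = derive_seed(cfg$global_seed,
                                                  100L + fold$fold_id))
      native <- session$bolds$VS[[run_idx]]
      skip <- round(delay_s * native$fs_hz)
      r_low <- downsample_check(fr$y_pred,
                                native$values[(skip + 1):length(native$values)],
                                fs_pred = cfg$fs_common,
                                tr_s = 1 / native$fs_hz)
      ev_run <- events[events$run_id == fold$test_run, ]
      fv <- functional_validity(fr$y_pred, ev_run, cfg$fs_common,
                                offset_s = delay_s)
      roi_series <- c(
        list(VS = fr$y_true),
        stats::setNames(lapply(cfg$evaluation$rois, function(roi)
          align_roi_values(session$bolds[[roi]][[run_idx]],
                           length(fr$y_pred), cfg$fs_common, delay_s)),
          cfg$evaluation$rois))
      nuis <- cbind(win = event_regressor(ev_run, "win", cfg$fs_common,
                                          length(fr$y_pred), delay_s),
                    loss = event_regressor(ev_run, "loss", cfg$fs_common,
                                           length(fr$y_pred), delay_s))
      spec <- specificity_report(fr$y_pred, roi_series, nuisance = nuis)
      orc <- if (!is.null(session$truth) &&
                 inherits(cfg$synthetic, "synthetic_config"))
        oracle_envelope_r(session$truth, native) else NA_real_
      list(pv = pv, r_low = r_low, fv = fv, spec = spec, oracle = orc)
    })

    dl_folds[[fold$fold_id]] <- list(
      fold_id = fold$fold_id, test_run = fold$test_run, r = fr$r,
      permutation_p = ev_fold$pv$p, r_downsampled = ev_fold$r_low,
      beta_win = ev_fold$fv$beta_win, beta_loss = ev_fold$fv$beta_loss,
      roi_r = stats::setNames(ev_fold$spec$r, ev_fold$spec$roi),
      model = fr$model, y_true = fr$y_true, y_pred = fr$y_pred,
      history = fr$history, stop_reason = fr$stop_reason,
      pair = pairs[[fold$test_run]])
    linear_folds[[fold$fold_id]] <- lf
    oracle_r <- c(oracle_r, ev_fold$oracle)
  }

  say("stage: group tests")
  report <- group_tests(dl_folds, linear_folds)
  report$per_fold$r_downsampled <-
    vapply(dl_folds, `[[`, numeric(1), "r_downsampled")
  report$per_fold$permutation_p <-
    vapply(dl_folds, `[[`, numeric(1), "permutation_p")
  report$summary$r_downsampled <-
    c(mean = mean(report$per_fold$r_downsampled),
      sd = stats::sd(report$per_fold$r_downsampled),
      min = min(report$per_fold$r_downsampled),
      max = max(report$per_fold$r_downsampled))

  say("stage: interpretability")
  interp <- stage("interpret", NA, top_branches_report(
    lapply(dl_folds, `[[`, "model"),
    lapply(dl_folds, `[[`, "pair"),
    k = min(cfg$interpret$k_top, cfg$model$n_branches)))

  result <- list(report = report, dl_folds = dl_folds,
                 linear_folds = linear_folds, interpret = interp,
                 oracle_r = oracle_r, config = cfg)
  if (!is.null(cfg$output_dir)) write_experiment_bundle(result, cfg$output_dir)
  result
}

config_as_plain_list <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, "source_spec") || inherits(x, "synthetic_config") ||
        inherits(x, "model_config") || inherits(x, "train_config") ||
        inherits(x, "loss_config") || inherits(x, "experiment_config"))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  strip(cfg)
}

write_experiment_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_as_plain_list(result$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.table(result$report$per_fold, file.path(dir, "per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$report$tests, file.path(dir, "tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(result$interpret, function(b)
      list(rank = b$rank, spatial_pattern = b$spatial_pattern,
           freq_hz = b$freq_hz, freq_profile = b$freq_profile,
           mean_importance = b$mean_importance)),
    file.path(dir, "interpret.json"), auto_unbox = TRUE, digits = NA)
  for (f in result$dl_folds) {
    utils::write.table(
      data.frame(time = (seq_along(f$y_true) - 1) /
                   result$config$fs_common,
                 y_true = f$y_true, y_pred = f$y_pred),
      file.path(dir, sprintf("fold%02d_prediction.tsv", f$fold_id)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an experiment configuration from YAML
#'
#' Maps a nested YAML document through the config constructors, so every
#' invariant is checked on load. Fields omitted in the file keep the
#' constructor defaults; a shipped profile lives at
#' `system.file("config", "desk_scale.yaml", package = "eegbold")`.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort_invalid(paste0("cannot parse config: ", conditionMessage(e))))
  build <- function(ctor, fields, extra = list()) {
    do.call(ctor, c(fields %||% list(), extra))
  }
  syn_fields <- y$synthetic %||% list()
  if (!is.null(syn_fields$n_channels) && is.null(syn_fields$sources))
    syn_fields$sources <- default_sources(syn_fields$n_channels)
  if (is.null(syn_fields$seed) && !is.null(y$global_seed))
    syn_fields$seed <- derive_seed(y$global_seed, 1L)
  experiment_config(
    synthetic = build(synthetic_config, syn_fields),
    model = build(model_config, y$model),
    train = build(train_config, c(y$train, list(seed = y$global_seed %||% 1))),
    loss = build(loss_config, y$loss),
    n_folds = y$n_folds %||% 4,
    fs_common = y$fs_common %||% 100,
    evaluation = utils::modifyList(
      list(n_surrogates = 1000, alpha = 0.05, rois = c("VC", "PMC", "STN")),
      y$evaluation %||% list()),
    interpret = utils::modifyList(list(k_top = 3), y$interpret %||% list()),
    output_dir = y$output_dir,
    global_seed = y$global_seed %||% 1)
}
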