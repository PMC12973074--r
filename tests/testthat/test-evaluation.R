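test_that("pearson_r matches hand evaluations and guards degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r0 <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r0, 0)
  expect_error(pearson_r(1:3, 1:4), class = "eegbold_invalid_argument")
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  for (n in c(128, 255)) {
    y <- as.numeric(arima.sim(list(ar = 0.8), n))
    s <- phase_randomize(y, seed = 3)
    expect_true(is.numeric(s) && all(is.finite(s)))
    a0 <- Mod(fft(y)); a1 <- Mod(fft(s))
    expect_lt(max(abs(a0 - a1) / (a0 + 1e-12)), 1e-9)
  }
  expect_equal(phase_randomize(rep(2, 16), seed = 1), rep(2, 16),
               tolerance = 1e-12)
  # a pure sinusoid maps to a phase-shifted sinusoid of the same bin
  t <- 0:127
  y <- sin(2 * pi * 8 * t / 128)
  s <- phase_randomize(y, seed = 9)
  expect_equal(Mod(fft(s))[9], Mod(fft(y))[9], tolerance = 1e-9)
  expect_equal(sum(Mod(fft(s))[-c(9, 128 - 7)] > 1e-6), 0)
})

test_that("the permutation p-value uses the add-one percentile rule", {
  set.seed(8)
  x <- rnorm(300)
  y <- x + rnorm(300, sd = 0.2) # strong signal: beats every surrogate
  pv <- permutation_pvalue(y, x, n_surrogates = 1000, seed = 2)
  expect_equal(pv$p, 1 / 1001, tolerance = 1e-12)
  expect_length(pv$null_rs, 1000)
  expect_error(permutation_pvalue(y, x, n_surrogates = 0),
               class = "eegbold_invalid_argument")
})

test_that("the downsampling control reproduces perfect agreement", {
  set.seed(3)
  truth_native <- rnorm(60)
  # a prediction that holds each volume's value across its TR decimates
  # back to the native series exactly
  y_pred <- rep(truth_native, each = 200)
  r_low <- downsample_check(y_pred, truth_native, fs_pred = 100, tr_s = 2)
  expect_equal(r_low, 1, tolerance = 1e-9)
  expect_error(downsample_check(y_pred[1:100], truth_native),
               class = "eegbold_invalid_argument")
})

test_that("functional validity recovers known event coefficients", {
  cfg <- synthetic_config(n_channels = 4, n_runs = 1, trials_per_run = 20,
                          volumes_per_run = 110,
                          sources = default_sources(4), seed = 12)
  ev <- make_task_events(cfg)
  fs <- 10
  n <- 110 * 2 * fs
  win <- event_regressor(ev, "win", fs, n)
  loss <- event_regressor(ev, "loss", fs, n)
  set.seed(5)
  y <- 2 * win + 1 * loss + rnorm(n, sd = 0.1)
  fv <- functional_validity(y, ev, fs)
  expect_equal(fv$beta_win, 2, tolerance = 0.1)
  expect_equal(fv$beta_loss, 1, tolerance = 0.1)
})

test_that("specificity reporting matches simple-regression identities", {
  set.seed(6)
  pred <- rnorm(400)
  rois <- list(VS = pred * 0.8 + rnorm(400, sd = 0.5),
               VC = rnorm(400),
               PMC = -0.3 * pred + rnorm(400))
  rep <- specificity_report(pred, rois)
  expect_equal(rep$roi, c("VS", "VC", "PMC"))
  expect_equal(sign(rep$glm_beta), sign(rep$r))
  expect_gt(rep$r[1], max(abs(rep$r[2:3])))
  expect_error(specificity_report(pred, setNames(rois, c("A", "A", "B"))),
               class = "eegbold_invalid_argument")
})

test_that("group tests equal the textbook paired-t computation", {
  mk <- function(id, r, bw, bl, roi)
    list(fold_id = id, r = r, beta_win = bw, beta_loss = bl, roi_r = roi)
  r_dl <- c(0.31, 0.28, 0.40, 0.22, 0.35)
  r_li <- c(0.20, 0.25, 0.28, 0.11, 0.30)
  dl <- lapply(1:5, function(i)
    mk(i, r_dl[i], 0.5 + 0.1 * i, 0.3, c(VS = r_dl[i], VC = 0.05 * i)))
  li <- lapply(1:5, function(i) mk(i, r_li[i], NULL, NULL, NULL))
  rep <- group_tests(dl, li)
  d <- r_dl - r_li
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  row <- rep$tests[rep$tests$contrast == "r: DL vs linear", ]
  expect_equal(row$t, t_manual, tolerance = 1e-9)
  expect_equal(row$df, 4)
  expect_equal(rep$summary$r_dl[["mean"]], mean(r_dl), tolerance = 1e-12)
  expect_equal(rep$summary$r_dl[["min"]], min(r_dl))
  # identical series are flagged, not given a finite statistic
  same <- group_tests(dl, dl)
  expect_true(is.na(same$tests[same$tests$contrast == "r: DL vs linear", "t"]))
  expect_error(group_tests(dl, li[c(2:5, 1)]),
               class = "eegbold_invalid_argument")
})
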