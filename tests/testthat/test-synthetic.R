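test_that("task events are balanced, ordered and seeded", {
  cfg <- synthetic_config()
  ev <- make_task_events(cfg)
  expect_equal(nrow(ev), 400)
  for (r in unique(ev$run_id)) {
    evr <- ev[ev$run_id == r, ]
    expect_equal(nrow(evr), 100)
    expect_equal(sum(evr$outcome == "win"), 50)
    expect_equal(sum(evr$outcome == "loss"), 50)
    expect_true(all(diff(evr$onset_s) > 0))
    expect_true(all(evr$onset_s + evr$duration_s <= 530 * 2))
  }
  expect_identical(ev, make_task_events(cfg))
  expect_error(make_task_events(synthetic_config(trials_per_run = 9,
                                                 volumes_per_run = 60)),
               class = "eegbold_invalid_argument")
})

test_that("simulated sessions have the configured geometry and are seeded", {
  ses <- tiny_session(seed = 5)
  expect_length(ses$runs, 3)
  for (b in ses$bolds$VS) expect_length(b$values, 110)
  expect_equal(nrow(ses$runs[[1]]$data), 8)
  expect_equal(ses$runs[[1]]$channel_labels, paste0("e", 1:8))
  expect_true(all(vapply(ses$runs, function(r) all(is.finite(r$data)), TRUE)))
  ses2 <- tiny_session(seed = 5)
  expect_identical(ses$runs[[2]]$data, ses2$runs[[2]]$data)
  expect_identical(ses$bolds$VS[[1]]$values, ses2$bolds$VS[[1]]$values)
})

test_that("the planted source dominates the spectrum at its band", {
  ses <- tiny_session(seed = 2)
  pat <- ses$truth$patterns[[1]]
  X <- ses$runs[[1]]$data
  spec_of <- function(v) {
    pg <- stats::spec.pgram(ts(as.numeric(v %*% X), frequency = 100),
                            plot = FALSE, spans = 31)
    pg
  }
  on_pat <- spec_of(pat)
  # reference: spectra of random unit projections carry the shared 1/f
  # background; the pattern projection must show its excess at the band
  set.seed(1)
  ref <- rowMeans(vapply(1:8, function(i) {
    v <- rnorm(length(pat)); spec_of(v / sqrt(sum(v^2)))$spec
  }, numeric(length(on_pat$spec))))
  excess <- on_pat$spec / ref
  f_peak <- on_pat$freq[which.max(excess)]
  expect_gt(f_peak, 10 - 2)
  expect_lt(f_peak, 10 + 2)
})

test_that("uncoupled control ROIs are uncorrelated with the target", {
  ses <- tiny_session(seed = 9, n_runs = 1, volumes_per_run = 530,
                      trials_per_run = 100, control_coupling = 0)
  r <- cor(ses$bolds$VC[[1]]$values, ses$bolds$VS[[1]]$values)
  expect_lt(abs(r), 0.1)
})

test_that("symmetric win/loss gains produce no outcome effect in BOLD", {
  diffs <- vapply(1:20, function(sd) {
    src <- source_spec(rep(1, 4), 10, win_gain = 1.5, loss_gain = 1.5)
    cfg <- synthetic_config(n_channels = 4, n_runs = 1, trials_per_run = 20,
                            volumes_per_run = 110, sources = list(src),
                            seed = sd)
    ses <- simulate_session(cfg)
    ev <- ses$events
    fv <- functional_validity(ses$bolds$VS[[1]]$values, ev, fs_hz = 0.5)
    fv$beta_win - fv$beta_loss
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
  expect_lt(abs(mean(diffs)), 0.25)
})

test_that("the oracle noise ceiling matches the additive-noise closed form", {
  # noiseless regeneration is exact
  ses0 <- tiny_session(seed = 4, n_runs = 1, bold_noise_sd = 0)
  expect_equal(oracle_envelope_r(ses0$truth, ses0$bolds$VS[[1]]), 1,
               tolerance = 1e-6)
  # equal-variance noise: r = 1/sqrt(2); doubling the noise lowers r
  rs1 <- rs2 <- numeric(30)
  for (sd in 1:30) {
    s1 <- tiny_session(seed = sd, n_channels = 4, n_runs = 1,
                       trials_per_run = 10, bold_noise_sd = 1)
    s2 <- tiny_session(seed = sd, n_channels = 4, n_runs = 1,
                       trials_per_run = 10, bold_noise_sd = 2)
    rs1[sd] <- oracle_envelope_r(s1$truth, s1$bolds$VS[[1]])
    rs2[sd] <- oracle_envelope_r(s2$truth, s2$bolds$VS[[1]])
  }
  expect_equal(mean(rs1), 1 / sqrt(2), tolerance = 0.05)
  expect_lt(mean(rs2), mean(rs1))
})

test_that("session containers round-trip through plain text", {
  ses <- tiny_session(seed = 11, n_channels = 4, n_runs = 1,
                      volumes_per_run = 60, trials_per_run = 10)
  dir <- file.path(tempdir(), "ses-io")
  write_session(ses, dir)
  expect_true(file.exists(file.path(dir, "events.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_session(dir)
  expect_equal(back$runs[[1]]$data, ses$runs[[1]]$data, tolerance = 1e-5)
  expect_equal(back$bolds$VS[[1]]$values, ses$bolds$VS[[1]]$values,
               tolerance = 1e-5)
  expect_equal(back$events$onset_s, ses$events$onset_s)
  expect_equal(back$events$outcome, ses$events$outcome)
})
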