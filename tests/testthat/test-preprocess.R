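test_that("z-scoring standardizes, zeroes constants, and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore(c(5, 5, 5)), c(0, 0, 0))
  x <- rnorm(100)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-9)
  m <- zscore(matrix(rnorm(300), 3))
  expect_equal(unname(rowMeans(m)), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(m, 1, sd), rep(1, 3), tolerance = 1e-9)
  expect_error(zscore(1), class = "eegbold_invalid_argument")
})

test_that("common average referencing zeroes the channel mean everywhere", {
  eeg <- eeg_recording(matrix(rnorm(400), 4), paste0("e", 1:4), 100, "run1")
  ref <- common_average_reference(eeg)
  expect_equal(max(abs(colMeans(ref$data))), 0, tolerance = 1e-9)
  expect_equal(common_average_reference(ref)$data, ref$data, tolerance = 1e-12)
  one <- eeg_recording(matrix(rnorm(100), 1), "e1", 100, "run1")
  expect_error(common_average_reference(one),
               class = "eegbold_invalid_argument")
})

test_that("the band-pass filter keeps the passband and kills the stopband", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(f) eeg_recording(rbind(sin(2 * pi * f * t)), "e1", fs, "r")
  amp <- function(e) {
    mid <- floor(length(t) / 4):floor(3 * length(t) / 4)
    max(abs(e$data[1, mid]))
  }
  in_band <- bandpass(mk(10), 0.5, 45)
  expect_equal(amp(in_band), 1, tolerance = 0.05)
  mains <- bandpass(mk(60), 0.5, 45)
  expect_lt(20 * log10(amp(mains)), -40)
  drift <- bandpass(mk(0.05), 0.5, 45)
  expect_lt(20 * log10(amp(drift)), -20)
  expect_error(bandpass(mk(10), 50, 120), class = "eegbold_invalid_argument")
})

test_that("decimation to the common rate preserves passband amplitude", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  eeg <- eeg_recording(rbind(sin(2 * pi * 10 * t)), "e1", fs, "r")
  bold <- roi_bold_series(rnorm(6), 0.5, "VS", "target", "r")
  pair <- align_pair(eeg, bold, fs_common = 100, delay_s = 0)
  expect_equal(pair$fs_hz, 100)
  mid <- 200:800
  expect_equal(max(abs(pair$eeg$data[1, mid])), 1, tolerance = 0.05)
})

test_that("alignment pairs BOLD with EEG from delay_s earlier", {
  ses <- tiny_session(seed = 7, n_runs = 1, bold_noise_sd = 0, fs_hz = 100)
  pair <- align_pair(ses$runs[[1]], ses$bolds$VS[[1]], fs_common = 100,
                     delay_s = 6)
  expect_equal(ncol(pair$eeg$data), length(pair$bold$values))
  # the HRF-convolved true drive on the EEG timeline must align at lag 0:
  # align_pair has removed the 6 s transport delay to one-sample precision
  env2 <- ses$truth$runs[[1]]$envelope^2
  drive <- eegbold:::causal_conv(env2, canonical_hrf(100))
  n <- length(pair$bold$values)
  cc <- ccf(drive[seq_len(n)], pair$bold$values, lag.max = 200, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
  # without the shift the same peak sits at the transport delay (ccf's
  # negative lag k: drive at t-k predicts BOLD at t)
  pair0 <- align_pair(ses$runs[[1]], ses$bolds$VS[[1]], fs_common = 100,
                      delay_s = 0)
  n0 <- length(pair0$bold$values)
  cc0 <- ccf(drive[seq_len(n0)], pair0$bold$values, lag.max = 800,
             plot = FALSE)
  expect_equal(cc0$lag[which.max(cc0$acf)], -600, tolerance = 1)
  expect_error(align_pair(ses$runs[[1]], ses$bolds$VS[[1]], 100, 1e5),
               class = "eegbold_invalid_argument")
})

test_that("window extraction respects bounds, shapes and seeding", {
  ses <- tiny_session(seed = 3, n_runs = 1)
  pair <- align_pair(ses$runs[[1]], ses$bolds$VS[[1]], fs_common = 50)
  wins <- extract_windows(pair, window_s = 20, n_windows = 25, seed = 9)
  expect_length(wins, 25)
  n <- ncol(pair$eeg$data)
  for (w in wins) {
    expect_equal(dim(w$X), c(8, 1000))
    expect_length(w$y, 1000)
    expect_gte(w$start_index, 1)
    expect_lte(w$start_index + 999, n)
    expect_false(anyNA(w$X) || anyNA(w$y))
  }
  wins2 <- extract_windows(pair, window_s = 20, n_windows = 25, seed = 9)
  expect_identical(vapply(wins, `[[`, integer(1), "start_index"),
                   vapply(wins2, `[[`, integer(1), "start_index"))
  expect_error(extract_windows(pair, window_s = 1e4, n_windows = 1),
               class = "eegbold_invalid_argument")
})
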