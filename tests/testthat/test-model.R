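test_that("the compact block holds one spatial filter per branch", {
  m <- build_model(model_config(), seed = 1)
  expect_equal(dim(m$params$spat), c(16, 62))
  expect_equal(dim(m$params$tband), c(16, 51))
  expect_equal(dim(m$params$tsmooth), c(16, 51))
})

test_that("weight initialization is seeded and config-determined", {
  cfg <- tiny_model_cfg()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(m1$params$spat, m3$params$spat))
  expect_equal(n_parameters(m1), n_parameters(m3))
})

test_that("the compact block is positively homogeneous and zero-preserving", {
  m <- build_model(tiny_model_cfg(), seed = 2)
  X <- matrix(rnorm(4 * 200), 4)
  expect_equal(forward_compact(m, matrix(0, 4, 200)),
               matrix(0, 2, 200))
  expect_equal(forward_compact(m, 3 * X), 3 * forward_compact(m, X),
               tolerance = 1e-12)
  expect_error(forward_compact(m, matrix(0, 5, 200)),
               class = "eegbold_invalid_argument")
})

test_that("forward output length equals input length for admissible L", {
  m <- build_model(tiny_model_cfg(), seed = 3)
  for (L in c(8, 33, 57, 128, 1001)) {
    y <- forward(m, matrix(rnorm(4 * L), 4))
    expect_length(y, L)
  }
  md <- build_model(desk_scale_model_config(4), seed = 3)
  for (L in c(517, 1024)) expect_length(forward(md, matrix(rnorm(4 * L), 4)), L)
  expect_error(forward(md, matrix(rnorm(4 * 100), 4)),
               class = "eegbold_invalid_argument")
})

test_that("eval-mode forward passes are deterministic despite dropout", {
  m <- build_model(tiny_model_cfg(dropout = 0.5), seed = 4)
  X <- matrix(rnorm(4 * 300), 4)
  expect_identical(forward(m, X), forward(m, X))
})

test_that("every parameter group receives gradient on random data", {
  m <- build_model(tiny_model_cfg(), seed = 7)
  L <- 64; N <- 3
  X <- array(rnorm(4 * L * N), c(4, L, N))
  Y <- matrix(rnorm(L * N), L, N)
  fw <- forward(m, X, train = TRUE, keep_cache = TRUE)
  g <- eegbold:::backward(m, fw, eegbold:::loss_grad(Y, fw$out, loss_config()))
  norms <- vapply(g, function(x) sqrt(sum(x^2)), numeric(1))
  # conv biases feeding straight into batch norm are absorbed by the
  # normalization and legitimately carry ~zero gradient
  informative <- !grepl("^(enc|dec)[0-9]+_b$", names(norms))
  expect_true(all(norms[informative] > 0))
})

test_that("checkpoints round-trip and refuse a mismatching config", {
  m <- build_model(tiny_model_cfg(), seed = 8)
  m$trained <- TRUE
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path, expect_config = tiny_model_cfg())
  expect_identical(back$params, m$params)
  expect_true(back$trained)
  X <- matrix(rnorm(4 * 200), 4)
  expect_equal(forward(back, X), forward(m, X))
  expect_error(load_model(path, expect_config = desk_scale_model_config(4)),
               class = "eegbold_invalid_argument")
})

test_that("data-driven initialization recovers a planted component", {
  ses <- tiny_session(seed = 6, n_runs = 1)
  m <- build_model(model_config(n_channels = 8, n_branches = 2,
                                encoder_channels = 8),
                   seed = 1, init_eeg = ses$runs[[1]])
  pat <- ses$truth$patterns[[1]]
  cosines <- abs(apply(m$params$spat, 1, function(w)
    sum(w * pat) / sqrt(sum(w^2))))
  expect_gt(max(cosines), 0.9)
  best <- which.max(cosines)
  kr <- Mod(fft(m$params$tband[best, ]))[1:26]
  f_peak <- (which.max(kr) - 1) * 100 / 51
  expect_gt(f_peak, 7)
  expect_lt(f_peak, 13)
})
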