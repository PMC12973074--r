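#' Configuration of the interpretable regression autoencoder
#'
#' The architecture front-end is an interpretable compact block of
#' `n_branches` parallel streams — per branch a learnable spatial filter
#' (pointwise convolution over channels), a depthwise temporal band filter
#' (kernel `temporal_kernel`), ReLU rectification, and a depthwise temporal
#' smoothing filter of the same length, yielding an envelope-like series per
#' branch. A shared projection convolution feeds a three-block
#' conv/norm/GeLU/dropout encoder with stride-8 max pooling, mirrored by a
#' decoder (channels reduced by `decoder_channel_reduction`) with x8 linear
#' upsampling, a final linear resize to the input length, and a 1x1 readout
#' convolution.
#'
#' Spatial and temporal compact-block convolutions carry no bias so the
#' "spatial filter, band filter, power" reading of a branch survives
#' training.
#'
#' @param n_channels EEG channel count (62 at full scale).
#' @param n_branches compact-block branches (16 at full scale).
#' @param temporal_kernel depthwise kernel length (51).
#' @param projection_kernel shared projection kernel (3).
#' @param encoder_channels encoder width (128 at full scale).
#' @param encoder_kernel encoder/decoder conv kernel (3).
#' @param n_encoder_blocks encoder (= decoder) depth (3).
#' @param pool_stride max-pool stride per encoder block (8).
#' @param dropout_rate dropout rate (0.3).
#' @param decoder_channel_reduction decoder width divisor (4).
#' @param norm `"batch"` (default) or `"instance"` normalization.
#' @export
model_config <- function(n_channels = 62, n_branches = 16, temporal_kernel = 51,
                         projection_kernel = 3, encoder_channels = 128,
                         encoder_kernel = 3, n_encoder_blocks = 3,
                         pool_stride = 8, dropout_rate = 0.3,
                         decoder_channel_reduction = 4,
                         norm = c("batch", "instance")) {
  norm <- match.arg(norm)
  cfg <- list(n_channels = n_channels, n_branches = n_branches,
              temporal_kernel = temporal_kernel,
              projection_kernel = projection_kernel,
              encoder_channels = encoder_channels,
              encoder_kernel = encoder_kernel,
              n_encoder_blocks = n_encoder_blocks, pool_stride = pool_stride,
              dropout_rate = dropout_rate,
              decoder_channel_reduction = decoder_channel_reduction,
              norm = norm)
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

validate_model_config <- function(cfg) {
  counts <- c(cfg$n_channels, cfg$n_branches, cfg$temporal_kernel,
              cfg$projection_kernel, cfg$encoder_channels, cfg$encoder_kernel,
              cfg$n_encoder_blocks)
  check_that(all(counts >= 1), "all architecture counts must be >= 1")
  check_that(cfg$pool_stride >= 2, "pool_stride must be >= 2")
  check_that(cfg$dropout_rate >= 0 && cfg$dropout_rate < 1,
             "dropout_rate must lie in [0, 1)")
  check_that(cfg$temporal_kernel %% 2 == 1 && cfg$projection_kernel %% 2 == 1 &&
               cfg$encoder_kernel %% 2 == 1,
             "kernel lengths must be odd (same padding)")
  check_that(cfg$encoder_channels %% cfg$decoder_channel_reduction == 0,
             "encoder_channels must be divisible by decoder_channel_reduction")
  invisible(TRUE)
}

#' Desk-scale model profile
#'
#' The reduced architecture used for CPU-scale experiments and throughout
#' the test suite: fewer channels/branches and a narrower encoder, same
#' topology.
#' @param n_channels channel count of the data it will consume.
#' @export
desk_scale_model_config <- function(n_channels = 16) {
  model_config(n_channels = n_channels, n_branches = 4, encoder_channels = 32)
}

#' Build a model with seeded weight initialization
#'
#' Default initialization is seeded-random: He-scaled Gaussians for the
#' dense convolutions, windowed sinusoids at log-spaced frequencies
#' (random phase) for the temporal band kernels, and a positive tapered
#' average for the smoothing kernels.
#'
#' When `init_eeg` is supplied (one or more [eeg_recording()]s — in
#' cross-validation, the fold's training runs only), the compact block is
#' instead initialized data-driven and unsupervised: spatial filters start
#' at the leading principal components of the channel covariance, and each
#' branch's band kernel at the frequency where that component's amplitude
#' spectrum most exceeds the average component spectrum. This is a
#' warm start in the spirit of PCA/ICA-seeded EEG decoders; every
#' parameter remains trainable.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initial weights.
#' @param init_eeg optional [eeg_recording()] or list of them for
#'   data-driven compact-block initialization.
#' @return a `model_handle` environment holding `config`, `params`
#'   (named list of arrays), normalization buffers, and an interpolation
#'   cache.
#' @export
build_model <- function(config, seed = 1, init_eeg = NULL) {
  validate_model_config(config)
  C <- config$n_channels; B <- config$n_branches
  kt <- config$temporal_kernel; kp <- config$projection_kernel
  E <- config$encoder_channels; ke <- config$encoder_kernel
  D <- E %/% config$decoder_channel_reduction

  model <- new.env(parent = emptyenv())
  model$config <- config
  model$interp_cache <- new.env(parent = emptyenv())
  p <- list()
  bufs <- list()
  with_session_seed(seed, 0L, {
    gaussian <- function(...) array(stats::rnorm(prod(c(...))), c(...))
    he <- function(fan_in, ...) gaussian(...) * sqrt(2 / fan_in)
    p$spat <- gaussian(B, C) / sqrt(C)
    # band kernels start as windowed sinusoids at log-spaced frequencies
    # (random phase), so the branches cover the spectrum from the first
    # step; smoothing kernels start as a positive tapered average. Both
    # stay fully learnable.
    tt <- seq_len(kt) - (kt + 1) / 2
    cycles <- exp(seq(log(1.5), log(kt / 4), length.out = B))
    hann <- 0.5 * (1 + cos(pi * tt / ((kt + 1) / 2)))
    p$tband <- t(vapply(seq_len(B), function(b) {
      ph <- stats::runif(1, 0, 2 * pi)
      k0 <- hann * cos(2 * pi * cycles[b] * tt / kt + ph)
      k0 / sqrt(sum(k0^2))
    }, numeric(kt)))
    p$tsmooth <- matrix(rep(hann / sum(hann), each = B), B, kt) *
      (1 + 0.1 * gaussian(B, kt))
    p$proj_W <- he(B * kp, E, B, kp); p$proj_b <- numeric(E)
    for (i in seq_len(config$n_encoder_blocks)) {
      p[[paste0("enc", i, "_W")]] <- he(E * ke, E, E, ke)
      p[[paste0("enc", i, "_b")]] <- numeric(E)
      p[[paste0("enc", i, "_g")]] <- rep(1, E)
      p[[paste0("enc", i, "_beta")]] <- numeric(E)
      bufs[[paste0("enc", i, "_mean")]] <- numeric(E)
      bufs[[paste0("enc", i, "_var")]] <- rep(1, E)
    }
    for (i in seq_len(config$n_encoder_blocks)) {
      cin <- if (i == 1) E else D
      p[[paste0("dec", i, "_W")]] <- he(cin * ke, D, cin, ke)
      p[[paste0("dec", i, "_b")]] <- numeric(D)
      p[[paste0("dec", i, "_g")]] <- rep(1, D)
      p[[paste0("dec", i, "_beta")]] <- numeric(D)
      bufs[[paste0("dec", i, "_mean")]] <- numeric(D)
      bufs[[paste0("dec", i, "_var")]] <- rep(1, D)
    }
    p$head_W <- he(D, 1, D, 1); p$head_b <- 0
  })
  model$params <- p
  model$buffers <- bufs
  model$trained <- FALSE
  class(model) <- "model_handle"
  if (!is.null(init_eeg)) data_driven_init(model, init_eeg, seed)
  model
}

# PCA + spectral-excess warm start of the compact block (unsupervised;
# uses only the EEG handed in, never any target signal)
data_driven_init <- function(model, init_eeg, seed) {
  if (inherits(init_eeg, "eeg_recording")) init_eeg <- list(init_eeg)
  fs <- init_eeg[[1]]$fs_hz
  X <- do.call(cbind, lapply(init_eeg, function(e) e$data))
  C <- nrow(X)
  B <- model$config$n_branches
  kt <- model$config$temporal_kernel
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  n_pc <- min(B, C)

  seg <- min(ncol(X), round(4 * fs))
  fgrid <- (seq_len(seg %/% 2 + 1) - 1) * fs / seg
  spec <- vapply(seq_len(n_pc), function(i) {
    s <- as.numeric(eg$vectors[, i] %*% X)
    n_seg <- length(s) %/% seg
    rowMeans(vapply(seq_len(n_seg), function(j)
      Mod(stats::fft(s[((j - 1) * seg + 1):(j * seg)]))[seq_len(seg %/% 2 + 1)],
      numeric(seg %/% 2 + 1)))
  }, numeric(seg %/% 2 + 1))
  ref <- rowMeans(spec)
  sel <- fgrid >= 1.5 & fgrid <= fs / 2 - 2

  tt <- seq_len(kt) - (kt + 1) / 2
  hann <- 0.5 * (1 + cos(pi * tt / ((kt + 1) / 2)))
  with_session_seed(seed, 5L, {
    for (b in seq_len(n_pc)) {
      f0 <- fgrid[sel][which.max((spec[, b] / (ref + 1e-9))[sel])]
      model$params$spat[b, ] <- eg$vectors[, b]
      k0 <- hann * cos(2 * pi * f0 * tt / fs + stats::runif(1, 0, 2 * pi))
      model$params$tband[b, ] <- k0 / sqrt(sum(k0^2))
    }
  })
  invisible(model)
}

#' Number of trainable parameters
#' @param model a `model_handle`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

as_batch <- function(X, n_channels) {
  if (is.matrix(X)) dim(X) <- c(dim(X), 1L)
  check_that(length(dim(X)) == 3, "X must be a matrix or a `C x L x N` array")
  if (dim(X)[1] != n_channels)
    abort_invalid(sprintf("X has %d channels, model expects %d",
                          dim(X)[1], n_channels))
  X
}

#' Compact-block forward pass
#'
#' Runs only the interpretable front-end: per branch, spatial filter,
#' temporal band filter, ReLU, temporal smoothing. Output is the
#' envelope-like branch activity.
#'
#' @param model a `model_handle`.
#' @param X channels x L matrix (or a `C x L x N` batch array).
#' @param branch_mask optional logical vector over branches; masked-out
#'   branches emit zeros (used by ablation importance).
#' @return n_branches x L matrix (or a `B x L x N` array for a batch).
#' @export
forward_compact <- function(model, X, branch_mask = NULL) {
  single <- is.matrix(X)
  X <- as_batch(X, model$config$n_channels)
  check_that(dim(X)[2] >= model$config$temporal_kernel,
             "window shorter than the temporal kernel")
  out <- compact_fwd(model$params, X, branch_mask)$out
  if (single) out[, , 1] else out
}

compact_fwd <- function(p, X, branch_mask = NULL) {
  d <- dim(X)
  s <- unflat3(p$spat %*% flat3(X), d[2], d[3])          # spatial filters
  cb <- dwconv_fwd(s, p$tband)                            # band filters
  cr <- relu_fwd(cb$out)
  cs <- dwconv_fwd(cr$out, p$tsmooth)                     # smoothing
  out <- cs$out
  if (!is.null(branch_mask)) out[!branch_mask, , ] <- 0
  list(out = out, X = X, cb = cb, cr = cr, cs = cs, mask = branch_mask)
}

compact_bwd <- function(dy, cache, p) {
  if (!is.null(cache$mask)) dy[!cache$mask, , ] <- 0
  gs <- dwconv_bwd(dy, cache$cs, p$tsmooth)
  dr <- relu_bwd(gs$dx, cache$cr)
  gb <- dwconv_bwd(dr, cache$cb, p$tband)
  d <- dim(cache$X)
  dspat <- flat3(gb$dx) %*% t(flat3(cache$X))
  list(dspat = dspat, dtband = gb$dK, dtsmooth = gs$dK)
}

#' Full forward pass
#'
#' Maps a channels x L EEG window (or a batch of them) to a length-L BOLD
#' prediction. In eval mode (`train = FALSE`, the default) the pass is
#' deterministic: dropout is off and normalization uses running statistics.
#'
#' @param model a `model_handle`.
#' @param X channels x L matrix or a `C x L x N` array.
#' @param train logical; training mode (batch statistics, dropout active).
#' @param branch_mask optional logical mask over compact-block branches.
#' @param keep_cache internal; retain the cache for a backward pass.
#' @return length-L vector (or L x N matrix for a batch). With
#'   `keep_cache = TRUE`, a list `(out, cache)`.
#' @export
forward <- function(model, X, train = FALSE, branch_mask = NULL,
                    keep_cache = FALSE) {
  single <- is.matrix(X)
  X <- as_batch(X, model$config$n_channels)
  cfg <- model$config
  L <- dim(X)[2]
  if (L < cfg$pool_stride^cfg$n_encoder_blocks)
    abort_invalid(sprintf("window length %d shorter than pooling footprint %d",
                          L, cfg$pool_stride^cfg$n_encoder_blocks))
  p <- model$params
  bufs <- model$buffers
  caches <- list()

  cc <- compact_fwd(p, X, branch_mask)
  caches$compact <- cc
  cp <- conv1d_fwd(cc$out, p$proj_W, p$proj_b)
  caches$proj <- cp
  h <- cp$out

  for (i in seq_len(cfg$n_encoder_blocks)) {
    nm <- paste0("enc", i)
    cv <- conv1d_fwd(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    bn <- norm_fwd(cfg, cv$out, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                   bufs[[paste0(nm, "_mean")]], bufs[[paste0(nm, "_var")]], train)
    bufs[[paste0(nm, "_mean")]] <- bn$run_mean
    bufs[[paste0(nm, "_var")]] <- bn$run_var
    gl <- gelu_fwd(bn$out)
    dp <- dropout_fwd(gl$out, cfg$dropout_rate, train)
    mp <- maxpool_fwd(dp$out, cfg$pool_stride)
    caches[[nm]] <- list(cv = cv, bn = bn, gl = gl, dp = dp, mp = mp)
    h <- mp$out
  }

  for (i in seq_len(cfg$n_encoder_blocks)) {
    nm <- paste0("dec", i)
    cv <- conv1d_fwd(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    bn <- norm_fwd(cfg, cv$out, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                   bufs[[paste0(nm, "_mean")]], bufs[[paste0(nm, "_var")]], train)
    bufs[[paste0(nm, "_mean")]] <- bn$run_mean
    bufs[[paste0(nm, "_var")]] <- bn$run_var
    gl <- gelu_fwd(bn$out)
    dp <- dropout_fwd(gl$out, cfg$dropout_rate, train)
    up <- interp_fwd(dp$out, dim(dp$out)[2] * cfg$pool_stride, model$interp_cache)
    caches[[nm]] <- list(cv = cv, bn = bn, gl = gl, dp = dp, up = up)
    h <- up$out
  }

  fin <- interp_fwd(h, L, model$interp_cache)
  caches$final_up <- fin
  hd <- conv1d_fwd(fin$out, p$head_W, p$head_b)
  caches$head <- hd
  if (train) model$buffers <- bufs

  y <- hd$out
  dim(y) <- dim(y)[2:3]
  if (single && !keep_cache) return(y[, 1])
  if (!keep_cache) return(y)
  list(out = y, cache = caches, single = single)
}

norm_fwd <- function(cfg, x, gamma, beta, run_mean, run_var, train) {
  if (cfg$norm == "instance") {
    # per-sample, per-channel normalization; running buffers unused
    mu <- apply(x, c(1, 3), mean)
    v <- apply(x, c(1, 3), stats::var) * (dim(x)[2] - 1) / dim(x)[2]
    inv <- 1 / sqrt(v + 1e-5)
    xhat <- array(0, dim(x))
    for (n in seq_len(dim(x)[3]))
      xhat[, , n] <- (x[, , n] - mu[, n]) * inv[, n]
    return(list(out = gamma * xhat + beta, xhat = xhat, inv = inv,
                gamma = gamma, run_mean = run_mean, run_var = run_var,
                instance = TRUE))
  }
  bn_fwd(x, gamma, beta, run_mean, run_var, train)
}

norm_bwd <- function(dy, cache) {
  if (isTRUE(cache$instance)) {
    xhat <- cache$xhat
    dg <- rowSums(flat3(dy * xhat))
    db <- rowSums(flat3(dy))
    dxhat <- dy * cache$gamma
    dx <- array(0, dim(dy))
    for (n in seq_len(dim(dy)[3])) {
      md <- rowMeans(dxhat[, , n, drop = FALSE])
      mdx <- rowMeans(flat3(dxhat[, , n, drop = FALSE] * xhat[, , n, drop = FALSE]))
      dx[, , n] <- cache$inv[, n] *
        (dxhat[, , n] - md - xhat[, , n] * mdx)
    }
    return(list(dx = dx, dgamma = dg, dbeta = db))
  }
  bn_bwd(dy, cache)
}

# full backward pass; dy is [L, N]; returns named gradient list
backward <- function(model, fwd_result, dy) {
  cfg <- model$config
  p <- model$params
  caches <- fwd_result$cache
  grads <- list()

  d3 <- array(dy, c(1, dim(dy)))
  gh <- conv1d_bwd(d3, caches$head, p$head_W)
  grads$head_W <- gh$dW; grads$head_b <- gh$db
  h <- interp_bwd(gh$dx, caches$final_up)

  for (i in rev(seq_len(cfg$n_encoder_blocks))) {
    nm <- paste0("dec", i)
    ca <- caches[[nm]]
    h <- interp_bwd(h, ca$up)
    h <- dropout_bwd(h, ca$dp)
    h <- gelu_bwd(h, ca$gl)
    nb <- norm_bwd(h, ca$bn)
    grads[[paste0(nm, "_g")]] <- nb$dgamma
    grads[[paste0(nm, "_beta")]] <- nb$dbeta
    cb <- conv1d_bwd(nb$dx, ca$cv, p[[paste0(nm, "_W")]])
    grads[[paste0(nm, "_W")]] <- cb$dW
    grads[[paste0(nm, "_b")]] <- cb$db
    h <- cb$dx
  }

  for (i in rev(seq_len(cfg$n_encoder_blocks))) {
    nm <- paste0("enc", i)
    ca <- caches[[nm]]
    h <- maxpool_bwd(h, ca$mp)
    h <- dropout_bwd(h, ca$dp)
    h <- gelu_bwd(h, ca$gl)
    nb <- norm_bwd(h, ca$bn)
    grads[[paste0(nm, "_g")]] <- nb$dgamma
    grads[[paste0(nm, "_beta")]] <- nb$dbeta
    cb <- conv1d_bwd(nb$dx, ca$cv, p[[paste0(nm, "_W")]])
    grads[[paste0(nm, "_W")]] <- cb$dW
    grads[[paste0(nm, "_b")]] <- cb$db
    h <- cb$dx
  }

  gp <- conv1d_bwd(h, caches$proj, p$proj_W)
  grads$proj_W <- gp$dW; grads$proj_b <- gp$db
  gc <- compact_bwd(gp$dx, caches$compact, p)
  grads$spat <- gc$dspat
  grads$tband <- gc$dtband
  grads$tsmooth <- gc$dtsmooth
  grads
}

#' Save a model checkpoint
#'
#' Single RDS file with the architecture config embedded; [load_model()]
#' refuses a checkpoint whose embedded config disagrees with the one it is
#' asked to assume.
#' @param model a `model_handle`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               config_json = jsonlite::toJSON(unclass(model$config),
                                              auto_unbox = TRUE),
               params = model$params, buffers = model$buffers,
               trained = model$trained), path)
}

#' Load a model checkpoint
#' @param path checkpoint file written by [save_model()].
#' @param expect_config optional [model_config()]; mismatch is an error.
#' @export
load_model <- function(path, expect_config = NULL) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), character(0))])
  if (!is.null(expect_config) && !identical(unclass(cfg), unclass(expect_config)))
    abort_invalid("checkpoint config does not match the expected config")
  model <- build_model(cfg, seed = 1)
  model$params <- ck$params
  model$buffers <- ck$buffers
  model$trained <- isTRUE(ck$trained)
  model
}
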