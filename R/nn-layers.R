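# Minimal 1-D convolutional network primitives on batched arrays.
#
# Every activation is a [channels, time, batch] array; time-domain ops
# broadcast over the first dimension (R recycles length-C vectors along
# dim 1), and dense convolutions reduce to BLAS matrix products on the
# [C, time*batch] flattening. Each forward returns the output plus the
# cache its backward needs; backwards return the input gradient and the
# parameter gradients.

flat3 <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1], d[2] * d[3])
  a
}

unflat3 <- function(m, L, N) {
  dim(m) <- c(nrow(m), L, N)
  m
}

# zero-padded time shift: Y[, l, ] = X[, l + off, ]
shift_time <- function(a, off) {
  if (off == 0) return(a)
  d <- dim(a)
  y <- array(0, d)
  L <- d[2]
  if (off > 0) {
    if (off < L) y[, 1:(L - off), ] <- a[, (off + 1):L, ]
  } else {
    off <- -off
    if (off < L) y[, (off + 1):L, ] <- a[, 1:(L - off), ]
  }
  y
}

# dense same-padding conv, odd kernel; W is [Cout, Cin, k], b length Cout
conv1d_fwd <- function(x, W, b) {
  list(out = cpp_conv1d_fwd(x, W, b), x = x)
}

conv1d_bwd <- function(dy, cache, W) {
  r <- cpp_conv1d_bwd(dy, cache$x, W)
  list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

# depthwise same-padding conv; K is [C, k]; no bias
dwconv_fwd <- function(x, K) {
  list(out = cpp_dwconv_fwd(x, K), x = x)
}

dwconv_bwd <- function(dy, cache, K) {
  r <- cpp_dwconv_bwd(dy, cache$x, K)
  list(dx = r$dx, dK = r$dK)
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

gelu_fwd <- function(x) list(out = cpp_gelu_fwd(x), x = x)
gelu_bwd <- function(dy, cache) cpp_gelu_bwd(cache$x, dy)

# batch normalization per channel over (time, batch)
bn_fwd <- function(x, gamma, beta, run_mean, run_var, train, momentum = 0.1,
                   eps = 1e-5) {
  r <- cpp_bn_fwd(x, gamma, beta, run_mean, run_var, train, momentum, eps)
  list(out = r$out, xhat = r$xhat, inv = as.numeric(r$inv), gamma = gamma,
       run_mean = as.numeric(r$run_mean), run_var = as.numeric(r$run_var))
}

bn_bwd <- function(dy, cache) {
  r <- cpp_bn_bwd(dy, cache$xhat, cache$inv, cache$gamma)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- array(stats::runif(length(x)) < keep, dim(x)) / keep
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# non-overlapping max pooling along time, floor semantics
maxpool_fwd <- function(x, stride) {
  if (dim(x)[2] %/% stride < 1) abort_invalid("input too short for max pooling")
  r <- cpp_maxpool_fwd(x, stride)
  list(out = r$out, am = r$am, L_in = r$L_in, stride = stride)
}

maxpool_bwd <- function(dy, cache) {
  cpp_maxpool_bwd(dy, cache$am, cache$L_in, cache$stride)
}

# linear interpolation along time (align-corners = FALSE convention: out
# sample p maps to input position (p + 0.5) * L_in / L_out - 0.5,
# zero-based); index triplets are cached per (L_in, L_out)
interp_index <- function(L_in, L_out) {
  p <- seq_len(L_out) - 1
  src <- (p + 0.5) * L_in / L_out - 0.5
  i0 <- floor(src)
  w <- src - i0
  w[i0 < 0] <- 0
  list(i0 = as.integer(pmin(pmax(i0, 0), L_in - 1)),
       i1 = as.integer(pmin(i0 + 1, L_in - 1)),
       w = w, L_in = L_in)
}

interp_fwd <- function(x, L_out, cache_env) {
  key <- paste0(dim(x)[2], ">", L_out)
  idx <- cache_env[[key]]
  if (is.null(idx)) {
    idx <- interp_index(dim(x)[2], L_out)
    cache_env[[key]] <- idx
  }
  list(out = cpp_interp_fwd(x, idx$i0, idx$i1, idx$w), idx = idx)
}

interp_bwd <- function(dy, cache) {
  cpp_interp_bwd(dy, cache$idx$i0, cache$idx$i1, cache$idx$w,
                 cache$idx$L_in)
}
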