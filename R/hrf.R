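#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — a gamma-density peak minus a scaled
#' gamma-density undershoot — at a given rate, scaled to unit peak.
#' Defaults follow the widely used canonical parameterization: peak delay
#' 6 s, undershoot delay 16 s, both dispersions 1 s, peak:undershoot ratio 6.
#' With unit dispersion the mode of the positive lobe sits near 5 s.
#'
#' @param fs_hz sampling rate in Hz.
#' @param duration_s kernel length in seconds (>= 20 so the undershoot
#'   resolves; default 32).
#' @param peak_delay_s,undershoot_delay_s gamma "delay" parameters (shape x
#'   dispersion), in seconds.
#' @param peak_disp_s,undershoot_disp_s gamma dispersions in seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of `fs_hz * duration_s` samples, unit peak.
#' @examples
#' h <- canonical_hrf(100, 32)
#' which.max(h) / 100 # close to 5 s
#' @export
canonical_hrf <- function(fs_hz, duration_s = 32,
                          peak_delay_s = 6, undershoot_delay_s = 16,
                          peak_disp_s = 1, undershoot_disp_s = 1,
                          ratio = 6) {
  check_that(is.numeric(fs_hz) && length(fs_hz) == 1 && fs_hz > 0,
             "fs_hz must be a positive scalar")
  check_that(is.numeric(duration_s) && length(duration_s) == 1 && duration_s >= 20,
             "duration_s must be >= 20 seconds")
  n <- round(fs_hz * duration_s)
  t <- seq(0, by = 1 / fs_hz, length.out = n)
  h <- stats::dgamma(t, shape = peak_delay_s / peak_disp_s,
                     rate = 1 / peak_disp_s) -
    stats::dgamma(t, shape = undershoot_delay_s / undershoot_disp_s,
                  rate = 1 / undershoot_disp_s) / ratio
  h / max(h)
}

#' Event regressor: impulses convolved with the canonical HRF
#'
#' Places a unit impulse at the feedback onset of every event with the given
#' outcome, convolves with [canonical_hrf()], and truncates to `n_samples`.
#'
#' @param events data frame of task events (see [make_task_events()]), with
#'   columns `onset_s` and `outcome`.
#' @param outcome `"win"` or `"loss"`.
#' @param fs_hz sampling rate of the output regressor.
#' @param n_samples output length.
#' @param offset_s drop this many seconds from the start before returning;
#'   use the hemodynamic alignment delay so the regressor shares the
#'   timeline of an aligned prediction.
#' @return numeric vector of length `n_samples`.
#' @export
event_regressor <- function(events, outcome, fs_hz, n_samples, offset_s = 0) {
  check_that(outcome %in% c("win", "loss"), "outcome must be 'win' or 'loss'")
  check_that(n_samples >= 1 && fs_hz > 0, "need positive n_samples and fs_hz")
  n_full <- n_samples + round(offset_s * fs_hz)
  onsets <- events$onset_s[events$outcome == outcome]
  stick <- numeric(n_full)
  if (length(onsets)) {
    idx <- round(onsets * fs_hz) + 1L
    if (any(idx < 1L | idx > n_full))
      abort_invalid("event onset outside [0, n_samples/fs_hz)")
    for (i in idx) stick[i] <- stick[i] + 1
  }
  h <- canonical_hrf(fs_hz)
  reg <- causal_conv(stick, h)
  reg[(n_full - n_samples + 1L):n_full]
}

# causal FFT convolution truncated to length(x)
causal_conv <- function(x, h) {
  n <- length(x)
  m <- stats::nextn(n + length(h) - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                       stats::fft(c(h, numeric(m - length(h)))), inverse = TRUE)) / m
  y[seq_len(n)]
}
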