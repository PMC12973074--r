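#' One run of multichannel EEG
#'
#' @param data channels x samples numeric matrix.
#' @param channel_labels character vector, one per row of `data`.
#' @param fs_hz sampling rate in Hz.
#' @param run_id run identifier.
#' @export
eeg_recording <- function(data, channel_labels, fs_hz, run_id) {
  check_that(is.matrix(data) && all(is.finite(data)), "EEG data must be a finite matrix")
  check_that(length(channel_labels) == nrow(data),
             "channel_labels must match the number of rows")
  check_that(fs_hz > 0, "fs_hz must be positive")
  structure(list(data = data, channel_labels = as.character(channel_labels),
                 fs_hz = fs_hz, run_id = run_id),
            class = "eeg_recording")
}

#' One ROI's BOLD time series for one run
#'
#' @param values numeric vector.
#' @param fs_hz sampling rate in Hz (1/TR natively, the common rate after
#'   interpolation).
#' @param roi_label ROI name, e.g. `"VS"`.
#' @param role `"target"` or `"control"`.
#' @param run_id run identifier.
#' @export
roi_bold_series <- function(values, fs_hz, roi_label, role, run_id) {
  check_that(all(is.finite(values)), "BOLD values must be finite")
  check_that(fs_hz > 0, "fs_hz must be positive")
  check_that(role %in% c("target", "control"), "role must be target or control")
  structure(list(values = as.numeric(values), fs_hz = fs_hz,
                 roi_label = roi_label, role = role, run_id = run_id),
            class = "roi_bold_series")
}

#' Z-score a vector or the rows of a matrix
#'
#' Per-channel mean 0 and unit sample SD; constant channels map to
#' all-zeros rather than NaN.
#'
#' @param x numeric vector, or channels x samples matrix (scored per row).
#' @export
zscore <- function(x) {
  if (is.matrix(x)) {
    check_that(ncol(x) >= 2, "need at least 2 samples per channel")
    mu <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    s[s == 0] <- Inf # constant rows -> zeros
    (x - mu) / s
  } else {
    check_that(length(x) >= 2, "need at least 2 samples")
    s <- stats::sd(x)
    if (s == 0) return(numeric(length(x)))
    (x - mean(x)) / s
  }
}

#' Re-reference EEG to a common average montage
#'
#' Subtracts the across-channel mean at every sample.
#' @param eeg an [eeg_recording()].
#' @export
common_average_reference <- function(eeg) {
  check_that(inherits(eeg, "eeg_recording"), "eeg must be an eeg_recording")
  if (nrow(eeg$data) < 2) abort_invalid("need at least 2 channels to re-reference")
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Zero-phase band-pass filter
#'
#' 6th-order Butterworth applied forward-backward (`filtfilt`), so the
#' passband is phase-neutral and stopband attenuation is doubled (a 60 Hz
#' mains tone is suppressed by more than 40 dB under the default
#' 0.5-45 Hz broadband window).
#'
#' @param eeg an [eeg_recording()].
#' @param lo_hz,hi_hz band edges in Hz; `0 < lo < hi < ` Nyquist.
#' @param order Butterworth order (6; orders above ~6 go numerically
#'   unstable for wide bands).
#' @export
bandpass <- function(eeg, lo_hz = 0.5, hi_hz = 45, order = 6) {
  check_that(inherits(eeg, "eeg_recording"), "eeg must be an eeg_recording")
  nyq <- eeg$fs_hz / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq))
    abort_invalid("band must satisfy 0 < lo < hi < Nyquist")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  eeg$data <- t(apply(eeg$data, 1, function(ch) signal::filtfilt(bf, ch)))
  eeg
}

# anti-alias filter + take-every-q decimation (integer factor)
decimate_eeg <- function(data, fs_in, fs_out) {
  if (fs_in == fs_out) return(data)
  q <- fs_in / fs_out
  check_that(abs(q - round(q)) < 1e-9, "EEG rate must be an integer multiple of the common rate")
  q <- round(q)
  lp <- signal::butter(8, 0.8 / q, type = "low")
  filtered <- t(apply(data, 1, function(ch) signal::filtfilt(lp, ch)))
  filtered[, seq(1, ncol(data), by = q), drop = FALSE]
}

#' Align one EEG run with one BOLD run at a common rate
#'
#' EEG is anti-alias filtered and decimated to `fs_common`; BOLD is
#' cubic-spline interpolated (`method = "linear"` switches to linear) to the
#' same rate. The hemodynamic contract is `y(t)` paired with
#' `X(t - delay_s)`: the EEG is advanced by `delay_s` and both series are
#' trimmed (never padded) so lengths match. Sample `i` of the pair
#' corresponds to absolute run time `(delay_s + (i-1)/fs)` on the BOLD
#' timeline.
#'
#' @param eeg an [eeg_recording()] (`fs_hz >= fs_common`).
#' @param bold a [roi_bold_series()] at its native rate.
#' @param fs_common target rate in Hz (default 100).
#' @param delay_s hemodynamic shift in seconds (default 6).
#' @param method `"spline"` (default) or `"linear"` BOLD interpolation.
#' @return an `aligned_pair`: `eeg`, `bold` (both at `fs_common`, equal
#'   lengths), `fs_hz`, `hrf_delay_s`, `run_id`.
#' @export
align_pair <- function(eeg, bold, fs_common = 100, delay_s = 6,
                       method = c("spline", "linear")) {
  method <- match.arg(method)
  check_that(inherits(eeg, "eeg_recording") && inherits(bold, "roi_bold_series"),
             "need an eeg_recording and a roi_bold_series")
  check_that(eeg$fs_hz >= fs_common, "eeg$fs_hz must be >= fs_common")
  check_that(delay_s >= 0, "delay_s must be >= 0")

  x <- decimate_eeg(eeg$data, eeg$fs_hz, fs_common)
  t_bold <- (seq_along(bold$values) - 1) / bold$fs_hz
  t_out <- seq(0, t_bold[length(t_bold)], by = 1 / fs_common)
  y <- if (bold$fs_hz == fs_common) bold$values else if (method == "spline")
    stats::spline(t_bold, bold$values, xout = t_out)$y
  else stats::approx(t_bold, bold$values, xout = t_out)$y

  d <- round(delay_s * fs_common)
  n <- min(ncol(x), length(y))
  if (d >= n) abort_invalid("delay longer than the recording")
  x_al <- x[, seq_len(n - d), drop = FALSE]        # EEG from run start
  y_al <- y[(d + 1):n]                             # BOLD from delay onward
  structure(list(
    eeg = eeg_recording(x_al, eeg$channel_labels, fs_common, eeg$run_id),
    bold = roi_bold_series(y_al, fs_common, bold$roi_label, bold$role, bold$run_id),
    fs_hz = fs_common, hrf_delay_s = delay_s, run_id = eeg$run_id
  ), class = "aligned_pair")
}

#' Draw random training windows from an aligned pair
#'
#' Start indices are uniform over the admissible range (overlap permitted),
#' seeded; each window is the `channels x L` EEG matrix with its length-`L`
#' BOLD vector, `L = window_s * fs`.
#'
#' @param pair an `aligned_pair`.
#' @param window_s window duration in seconds (160 at the full scale).
#' @param n_windows number of windows to draw.
#' @param seed integer seed.
#' @return list of `training_window` objects: `X`, `y`, `start_index`,
#'   `run_id`.
#' @export
extract_windows <- function(pair, window_s, n_windows, seed = 1) {
  check_that(inherits(pair, "aligned_pair"), "pair must be an aligned_pair")
  L <- round(window_s * pair$fs_hz)
  n <- ncol(pair$eeg$data)
  if (L > n) abort_invalid("window longer than the recording")
  starts <- with_session_seed(seed, 0L, sample.int(n - L + 1L, n_windows, replace = TRUE))
  lapply(starts, function(s0) {
    structure(list(
      X = pair$eeg$data[, s0:(s0 + L - 1L), drop = FALSE],
      y = pair$bold$values[s0:(s0 + L - 1L)],
      start_index = s0, run_id = pair$run_id
    ), class = "training_window")
  })
}
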