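#' Spatio-spectral source specification for the synthetic generator
#'
#' A planted EEG source: a unit-norm spatial pattern over channels, a
#' band-limited oscillation around `center_freq_hz`, a baseline amplitude,
#' and multiplicative win/loss gains applied for a short window after each
#' feedback onset. Source 1 of a session drives the target-ROI BOLD through
#' `envelope^coupling_exponent` (see [synthetic_config()]).
#'
#' @param spatial_pattern numeric vector over channels; normalized to unit
#'   Euclidean norm.
#' @param center_freq_hz,bandwidth_hz band center and width in Hz.
#' @param baseline_amp baseline amplitude (arbitrary units, relative to the
#'   unit-SD band-limited carrier).
#' @param win_gain,loss_gain multiplicative amplitude modulation (>= 0)
#'   applied for `modulation_s` seconds after win/loss feedback.
#' @export
source_spec <- function(spatial_pattern, center_freq_hz, bandwidth_hz = 4,
                        baseline_amp = 2, win_gain = 2, loss_gain = 0.5) {
  check_that(is.numeric(spatial_pattern) && length(spatial_pattern) >= 1 &&
               all(is.finite(spatial_pattern)) && any(spatial_pattern != 0),
             "spatial_pattern must be a nonzero finite vector")
  check_that(center_freq_hz > 0, "center_freq_hz must be positive")
  check_that(bandwidth_hz > 0 && win_gain >= 0 && loss_gain >= 0 &&
               baseline_amp > 0, "bad source parameters")
  structure(list(
    spatial_pattern = spatial_pattern / sqrt(sum(spatial_pattern^2)),
    center_freq_hz = center_freq_hz,
    bandwidth_hz = bandwidth_hz,
    baseline_amp = baseline_amp,
    win_gain = win_gain,
    loss_gain = loss_gain
  ), class = "source_spec")
}

#' Default planted sources
#'
#' Source 1 (BOLD-coupled): 10 Hz oscillation with a smooth unit-norm
#' pattern over a posterior-like contiguous block of channels. Optional
#' source 2 (a distractor, never coupled): 6 Hz with a frontal-like block.
#'
#' @param n_channels channel count.
#' @param n_sources 1 or 2.
#' @export
default_sources <- function(n_channels, n_sources = 1) {
  bump <- function(center_frac, width_frac) {
    c0 <- center_frac * n_channels
    w <- width_frac * n_channels
    p <- exp(-0.5 * ((seq_len(n_channels) - c0) / w)^2)
    p / sqrt(sum(p^2))
  }
  s1 <- source_spec(bump(0.7, 0.12), center_freq_hz = 10)
  if (n_sources == 1) return(list(s1))
  s2 <- source_spec(bump(0.25, 0.12), center_freq_hz = 6,
                    win_gain = 1, loss_gain = 1)
  list(s1, s2)
}

#' Synthetic simultaneous EEG-fMRI session configuration
#'
#' Defaults emulate the acquisition geometry of a four-run gambling session:
#' 62-channel EEG at a 100 Hz common rate, 4 runs of 100 trials with equally
#' probable win/loss feedback, 530 BOLD volumes per run at TR = 2 s, and a
#' 6 s hemodynamic transport delay. The target ROI ("VS") is driven by the
#' HRF-convolved, delayed `envelope^coupling_exponent` of source 1; the
#' control ROIs ("VC", "PMC", "STN") receive only a weak copy of that drive.
#'
#' `bold_noise_sd` is expressed in units of the standardized clean BOLD
#' drive, so `bold_noise_sd = 1` puts the noise ceiling (the correlation of
#' the clean drive with the noisy BOLD) near 1/sqrt(2) ~= 0.71.
#'
#' @param n_channels,fs_hz,n_runs,trials_per_run,tr_s,volumes_per_run
#'   acquisition geometry.
#' @param trial_duration_s trial length; feedback onset is at trial start
#'   + 5 s, modulation lasts `modulation_s` = 2 s.
#' @param hrf_delay_s transport delay between EEG and BOLD timelines.
#' @param sources list of [source_spec()]; source 1 drives the target ROI.
#' @param eeg_noise list with `pink_sd`, `white_sd`, `slope` (1/f exponent).
#' @param bold_noise_sd additive BOLD noise SD (units of clean-drive SD).
#' @param control_coupling weight in `[0, 1)` of the target drive leaked
#'   into control ROIs.
#' @param coupling_exponent exponent applied to the source envelope before
#'   HRF convolution (2 = power coupling, a mild nonlinearity).
#' @param seed integer seed; identical configs give bit-identical sessions.
#' @export
synthetic_config <- function(n_channels = 62, fs_hz = 100, n_runs = 4,
                             trials_per_run = 100, trial_duration_s = 10,
                             tr_s = 2, volumes_per_run = 530,
                             hrf_delay_s = 6, sources = NULL,
                             eeg_noise = list(pink_sd = 1, white_sd = 0.5, slope = 1),
                             bold_noise_sd = 1, control_coupling = 0.15,
                             coupling_exponent = 2, modulation_s = 2,
                             feedback_offset_s = 5, seed = 1) {
  if (is.null(sources)) sources <- default_sources(n_channels)
  cfg <- list(n_channels = n_channels, fs_hz = fs_hz, n_runs = n_runs,
              trials_per_run = trials_per_run,
              trial_duration_s = trial_duration_s, tr_s = tr_s,
              volumes_per_run = volumes_per_run, hrf_delay_s = hrf_delay_s,
              sources = sources, eeg_noise = eeg_noise,
              bold_noise_sd = bold_noise_sd,
              control_coupling = control_coupling,
              coupling_exponent = coupling_exponent,
              modulation_s = modulation_s,
              feedback_offset_s = feedback_offset_s, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  check_that(cfg$n_channels >= 1 && cfg$fs_hz > 0 && cfg$n_runs >= 1 &&
               cfg$trials_per_run >= 1 && cfg$tr_s > 0 &&
               cfg$volumes_per_run >= 1, "bad session geometry")
  check_that(cfg$volumes_per_run * cfg$tr_s >=
               cfg$trials_per_run * cfg$trial_duration_s,
             "run shorter than its trials: volumes_per_run * tr_s must cover trials")
  check_that(cfg$bold_noise_sd >= 0 && cfg$eeg_noise$pink_sd >= 0 &&
               cfg$eeg_noise$white_sd >= 0, "noise levels must be >= 0")
  check_that(cfg$control_coupling >= 0 && cfg$control_coupling < 1,
             "control_coupling must lie in [0, 1)")
  for (s in cfg$sources) {
    check_that(inherits(s, "source_spec"), "sources must be source_spec objects")
    if (s$center_freq_hz >= cfg$fs_hz / 2)
      abort_invalid("source center frequency at or above Nyquist")
    check_that(length(s$spatial_pattern) == cfg$n_channels,
               "spatial_pattern length must equal n_channels")
  }
  invisible(TRUE)
}

#' Task event table for one synthetic session
#'
#' Trials at fixed spacing within each run; feedback onset at trial start +
#' `feedback_offset_s`; outcomes are a seeded random permutation of exactly
#' half win, half loss per run (the instructed 50/50 outcome probability,
#' realized exactly); magnitudes are drawn from {5, 25}.
#'
#' @param cfg a [synthetic_config()].
#' @return data frame with columns `run_id`, `trial_index`, `onset_s`
#'   (feedback onset, seconds from run start), `duration_s`, `outcome`,
#'   `magnitude`.
#' @export
make_task_events <- function(cfg) {
  validate_synthetic_config(cfg)
  if (cfg$trials_per_run %% 2L != 0L)
    abort_invalid("trials_per_run must be even for exact win/loss balance")
  n <- cfg$trials_per_run
  rows <- with_session_seed(cfg$seed, 101L, {
    do.call(rbind, lapply(seq_len(cfg$n_runs), function(r) {
      outcome <- sample(rep(c("win", "loss"), each = n / 2))
      magnitude <- sample(c(5, 25), n, replace = TRUE)
      data.frame(
        run_id = paste0("run", r),
        trial_index = seq_len(n),
        onset_s = (seq_len(n) - 1) * cfg$trial_duration_s + cfg$feedback_offset_s,
        duration_s = cfg$modulation_s,
        outcome = outcome,
        magnitude = magnitude,
        stringsAsFactors = FALSE
      )
    }))
  })
  rownames(rows) <- NULL
  rows
}

# run `expr` under a derived seed without disturbing the caller's RNG state
with_session_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Small documented counter scheme: `(seed * 7919 + 104729 * stream)` folded
#' into the 31-bit signed-integer range.
#' @param seed integer global seed.
#' @param stream integer stream index.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483647)
}

# 1/f^slope amplitude-shaped Gaussian noise, unit SD, length n
pink_noise <- function(n, slope = 1) {
  m <- stats::nextn(n, 2)
  f <- stats::fft(stats::rnorm(m))
  freq <- pmin(0:(m - 1), m - (0:(m - 1))) # symmetric |f|, Hermitian-safe
  shape <- pmax(freq, 1)^(-slope / 2)
  x <- Re(stats::fft(f * shape, inverse = TRUE))[seq_len(n)] / m
  (x - mean(x)) / stats::sd(x)
}

# band-limited unit-SD Gaussian carrier
band_noise <- function(n, fs, lo, hi) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2000))
  x <- x[1001:(1000 + n)]
  x / stats::sd(x)
}

# analytic-signal magnitude (Hilbert envelope)
hilbert_env <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(f * h, inverse = TRUE) / n)
}

#' Simulate one synthetic simultaneous EEG-fMRI session
#'
#' For each run, every source emits a band-limited oscillation whose
#' amplitude is `baseline_amp`, multiplied by `win_gain` or `loss_gain` for
#' `modulation_s` seconds after each feedback onset. EEG is the sum of
#' pattern-projected sources plus 1/f and white sensor noise. The target
#' ROI's BOLD is the HRF-convolved `envelope^coupling_exponent` of source 1,
#' delayed by `hrf_delay_s`, sampled at the TR, noised, and z-scored;
#' control ROIs get `control_coupling` times the same standardized drive
#' plus independent unit noise.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `runs` (list of `eeg_recording`), `bolds` (map ROI
#'   label -> list of `roi_bold_series`), `events` (data frame), and `truth`
#'   (per-run envelopes, clean drives, source patterns/frequencies, config).
#' @export
simulate_session <- function(cfg) {
  validate_synthetic_config(cfg)
  check_that(length(cfg$sources) >= 1, "need at least one source")
  events <- make_task_events(cfg)
  fs <- cfg$fs_hz
  n_t <- round(cfg$volumes_per_run * cfg$tr_s * fs)
  hrf <- canonical_hrf(fs)
  rois <- c("VS", "VC", "PMC", "STN")

  runs <- vector("list", cfg$n_runs)
  bolds <- stats::setNames(lapply(rois, function(x) vector("list", cfg$n_runs)), rois)
  truth <- list(config = cfg, runs = vector("list", cfg$n_runs),
                patterns = lapply(cfg$sources, `[[`, "spatial_pattern"),
                frequencies = vapply(cfg$sources, `[[`, numeric(1), "center_freq_hz"))

  for (r in seq_len(cfg$n_runs)) {
    run_id <- paste0("run", r)
    ev <- events[events$run_id == run_id, ]
    with_session_seed(cfg$seed, 200L + r, {
      eeg <- matrix(0, cfg$n_channels, n_t)
      env1 <- NULL
      for (si in seq_along(cfg$sources)) {
        s <- cfg$sources[[si]]
        carrier <- band_noise(n_t, fs,
                              max(s$center_freq_hz - s$bandwidth_hz / 2, 0.1),
                              min(s$center_freq_hz + s$bandwidth_hz / 2, fs / 2 - 0.5))
        amp <- rep(s$baseline_amp, n_t)
        for (k in seq_len(nrow(ev))) {
          i0 <- round(ev$onset_s[k] * fs) + 1L
          i1 <- min(i0 + round(cfg$modulation_s * fs) - 1L, n_t)
          amp[i0:i1] <- amp[i0:i1] *
            if (ev$outcome[k] == "win") s$win_gain else s$loss_gain
        }
        sig <- carrier * amp
        eeg <- eeg + s$spatial_pattern %*% t(sig)
        if (si == 1L) env1 <- hilbert_env(sig)
      }
      for (ch in seq_len(cfg$n_channels)) {
        eeg[ch, ] <- eeg[ch, ] +
          cfg$eeg_noise$pink_sd * pink_noise(n_t, cfg$eeg_noise$slope) +
          cfg$eeg_noise$white_sd * stats::rnorm(n_t)
      }

      drive <- causal_conv(env1^cfg$coupling_exponent, hrf)
      d <- round(cfg$hrf_delay_s * fs)
      drive_delayed <- c(numeric(d), drive[seq_len(n_t - d)])
      vol_idx <- round((seq_len(cfg$volumes_per_run) - 1) * cfg$tr_s * fs) + 1L
      clean <- as.numeric(scale(drive_delayed[vol_idx]))

      labels <- paste0("e", seq_len(cfg$n_channels))
      # emitted EEG emulates preprocessed data: z-scored per channel
      runs[[r]] <- eeg_recording(zscore(eeg), labels, fs, run_id)
      bolds[["VS"]][[r]] <- roi_bold_series(
        as.numeric(scale(clean + cfg$bold_noise_sd * stats::rnorm(cfg$volumes_per_run))),
        fs_hz = 1 / cfg$tr_s, roi_label = "VS", role = "target", run_id = run_id)
      for (roi in c("VC", "PMC", "STN")) {
        bolds[[roi]][[r]] <- roi_bold_series(
          as.numeric(scale(cfg$control_coupling * clean + stats::rnorm(cfg$volumes_per_run))),
          fs_hz = 1 / cfg$tr_s, roi_label = roi, role = "control", run_id = run_id)
      }
      truth$runs[[r]] <- list(run_id = run_id, envelope = env1,
                               clean_bold = clean)
    })
  }
  list(runs = runs, bolds = bolds, events = events, truth = truth)
}

#' Noise-ceiling correlation between the true coupled drive and a noisy BOLD
#'
#' Recomputes the HRF-convolved, delayed, TR-sampled, standardized drive
#' from the ground-truth envelope and correlates it with the stored noisy
#' BOLD — the upper bound any decoder can reach on that run.
#'
#' @param truth `truth` record from [simulate_session()].
#' @param bold one `roi_bold_series` from the same session.
#' @export
oracle_envelope_r <- function(truth, bold) {
  cfg <- truth$config
  r <- match(bold$run_id, vapply(truth$runs, `[[`, character(1), "run_id"))
  if (is.na(r)) abort_internal("bold run not present in truth record")
  clean <- recompute_clean_drive(truth, r)
  if (length(clean) != length(bold$values))
    abort_internal("length mismatch between truth drive and BOLD after resampling")
  pearson_r(clean, bold$values)
}

recompute_clean_drive <- function(truth, r) {
  cfg <- truth$config
  fs <- cfg$fs_hz
  env <- truth$runs[[r]]$envelope
  drive <- causal_conv(env^cfg$coupling_exponent, canonical_hrf(fs))
  d <- round(cfg$hrf_delay_s * fs)
  drive_delayed <- c(numeric(d), drive[seq_len(length(env) - d)])
  vol_idx <- round((seq_len(cfg$volumes_per_run) - 1) * cfg$tr_s * fs) + 1L
  as.numeric(scale(drive_delayed[vol_idx]))
}
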