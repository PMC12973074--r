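#' Write a synthetic session to a plain-text container
#'
#' One directory per session: `meta.json` (rates, channel labels, run ids),
#' BIDS-style `events.tsv` (onset, duration, trial_type, run), per-run
#' `<run>_eeg.tsv` (one channel per column) and `<run>_bold_<roi>.tsv`
#' (time, value), and `truth.json` (source patterns, frequencies, seed).
#'
#' @param session list from [simulate_session()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$truth$config
  meta <- list(
    fs_hz = cfg$fs_hz, tr_s = cfg$tr_s,
    run_ids = vapply(session$runs, `[[`, character(1), "run_id"),
    channel_labels = session$runs[[1]]$channel_labels,
    rois = names(session$bolds)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)

  ev <- session$events
  utils::write.table(
    data.frame(onset = ev$onset_s, duration = ev$duration_s,
               trial_type = ev$outcome, run = ev$run_id),
    file.path(dir, "events.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  for (run in session$runs) {
    eeg_df <- as.data.frame(t(run$data))
    names(eeg_df) <- run$channel_labels
    utils::write.table(eeg_df, file.path(dir, paste0(run$run_id, "_eeg.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (roi in names(session$bolds)) {
    for (b in session$bolds[[roi]]) {
      utils::write.table(
        data.frame(time = (seq_along(b$values) - 1) / b$fs_hz,
                   value = b$values),
        file.path(dir, paste0(b$run_id, "_bold_", roi, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(patterns = session$truth$patterns,
         frequencies = session$truth$frequencies,
         seed = cfg$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session container written by [write_session()]
#'
#' Restores EEG recordings, per-ROI BOLD series, and the event table (the
#' ground-truth JSON is reloaded only if present; real data carry none).
#'
#' @param dir session directory.
#' @return list with `runs`, `bolds`, `events`, and (optionally) `truth`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  events <- data.frame(run_id = ev$run, onset_s = ev$onset,
                       duration_s = ev$duration, outcome = ev$trial_type,
                       stringsAsFactors = FALSE)
  runs <- lapply(meta$run_ids, function(rid) {
    m <- t(as.matrix(utils::read.delim(file.path(dir, paste0(rid, "_eeg.tsv")))))
    dimnames(m) <- NULL
    eeg_recording(m, meta$channel_labels, meta$fs_hz, rid)
  })
  bolds <- lapply(meta$rois, function(roi) {
    lapply(meta$run_ids, function(rid) {
      d <- utils::read.delim(file.path(dir, paste0(rid, "_bold_", roi, ".tsv")))
      roi_bold_series(d$value, 1 / meta$tr_s, roi,
                      if (roi == "VS") "target" else "control", rid)
    })
  })
  names(bolds) <- meta$rois
  out <- list(runs = runs, bolds = bolds, events = events)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) out$truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  out
}
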