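#' @keywords internal
abort_eegbold <- function(message, class) {
  stop(structure(
    class = c(paste0("eegbold_", class), "eegbold_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_invalid <- function(message) abort_eegbold(message, "invalid_argument")
abort_internal <- function(message) abort_eegbold(message, "internal_consistency")
abort_degenerate <- function(message) abort_eegbold(message, "degenerate_input")
abort_state <- function(message) abort_eegbold(message, "invalid_state")
abort_training <- function(message) abort_eegbold(message, "training_failure")

check_that <- function(ok, message) {
  if (!isTRUE(ok)) abort_invalid(message)
  invisible(TRUE)
}
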