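#' Read and write trial metadata
#'
#' Trial records travel as plain CSV with one row per trial and the column
#' layout of [simulate_behavior()] (times in ms, features as string enums),
#' so user data can be dropped into the pipeline in the same shape.
#'
#' @param records Trial records data.frame.
#' @param path CSV path.
#' @return `read_trial_records` returns the records data.frame;
#'   `write_trial_records` returns the path invisibly.
#' @export
write_trial_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "session_id", "task_type", "sample_color",
              "sample_motion", "test_color", "test_motion", "is_target",
              "outcome", "reaction_time_ms", "delay_ms")
  missing <- setdiff(needed, names(r))
  if (length(missing))
    stop("trial metadata missing column(s): ", paste(missing, collapse = ", "))
  r$is_target <- as.logical(r$is_target)
  r
}

#' Save or load a session recording
#'
#' Continuous recordings (channels x samples voltage matrix plus events) are
#' stored in R's native serialization; trial metadata should accompany them
#' as CSV via [write_trial_records()].
#'
#' @param recording A `session_recording`.
#' @param path File path (.rds).
#' @return `read_session_recording` returns the recording;
#'   `write_session_recording` returns the path invisibly.
#' @export
write_session_recording <- function(recording, path) {
  stopifnot(inherits(recording, "session_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_session_recording
#' @export
read_session_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "session_recording"))
    stop("file does not contain a session_recording")
  rec
}
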