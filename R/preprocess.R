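#' Preprocessing parameters
#'
#' The filter chain, applied in order: 50 Hz notch, 150 Hz low-pass,
#' resampling to 250 Hz, 1-80 Hz band-pass. All filters are zero-phase
#' (forward-backward) Butterworth IIR filters so that no phase distortion
#' biases onset latencies; resampling is polyphase with anti-aliasing.
#'
#' @param notch_hz Line-noise frequency to remove.
#' @param notch_bw_hz Stop-band width of the notch (Hz).
#' @param notch_order Butterworth order of the notch prototype.
#' @param lowpass_hz Anti-aliasing low-pass corner, applied before
#'   resampling.
#' @param lowpass_order Butterworth order of the low-pass.
#' @param resample_hz Target sampling rate.
#' @param bandpass_hz Length-2 pass band (Hz), applied after resampling.
#' @param bandpass_order Butterworth order of the band-pass prototype.
#' @param clip_threshold Fraction of the amplifier rail above which a sample
#'   counts as clipped.
#' @param clip_run_len Minimum number of consecutive clipped samples for a
#'   segment to be flagged.
#' @return An object of class `preproc_params`.
#' @export
preproc_params <- function(notch_hz = 50, notch_bw_hz = 10, notch_order = 2,
                           lowpass_hz = 150, lowpass_order = 4,
                           resample_hz = 250, bandpass_hz = c(1, 80),
                           bandpass_order = 4, clip_threshold = 0.99,
                           clip_run_len = 5) {
  stopifnot(length(bandpass_hz) == 2L, bandpass_hz[1] < bandpass_hz[2])
  if (bandpass_hz[2] >= lowpass_hz)
    stop("band-pass upper edge must be below the low-pass corner")
  if (bandpass_hz[2] >= resample_hz / 2)
    stop("band-pass upper edge must be below the resampled Nyquist")
  structure(list(notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
                 notch_order = notch_order, lowpass_hz = lowpass_hz,
                 lowpass_order = lowpass_order, resample_hz = resample_hz,
                 bandpass_hz = bandpass_hz, bandpass_order = bandpass_order,
                 clip_threshold = clip_threshold,
                 clip_run_len = clip_run_len),
            class = "preproc_params")
}

# zero-phase forward-backward IIR filtering of every channel; pad length is
# chosen from the filter's lowest critical frequency so edge transients have
# settled inside the padding
filtfilt_rows <- function(volt, filt, fs, edge_hz) {
  padlen <- max(3L * length(filt$a), as.integer(round(3 * fs / edge_hz)))
  for (ch in seq_len(nrow(volt)))
    volt[ch, ] <- cpp_filtfilt(filt$b, filt$a, volt[ch, ], padlen)
  volt
}

#' Preprocess a continuous recording
#'
#' Applies, in order: notch filter at 50 Hz, low-pass at 150 Hz, polyphase
#' resampling to 250 Hz, and a 1-80 Hz band-pass, all zero-phase. Event
#' sample indices are remapped to the new sampling rate.
#'
#' @param recording A `session_recording`.
#' @param params A [preproc_params()].
#' @return The recording at `params$resample_hz`, filtered, with events
#'   remapped.
#' @export
preprocess_continuous <- function(recording, params = preproc_params()) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$sampling_rate_hz
  if (ncol(recording$voltages) == 0L) stop("empty recording")
  if (fs <= 2 * params$lowpass_hz)
    stop("native rate must exceed twice the low-pass corner")
  if (params$resample_hz > fs)
    stop("resample_hz must not exceed the native rate")
  volt <- recording$voltages

  nyq <- fs / 2
  notch <- signal::butter(params$notch_order,
                          c(params$notch_hz - params$notch_bw_hz / 2,
                            params$notch_hz + params$notch_bw_hz / 2) / nyq,
                          type = "stop")
  volt <- filtfilt_rows(volt, notch, fs, params$notch_bw_hz)
  lp <- signal::butter(params$lowpass_order, params$lowpass_hz / nyq,
                       type = "low")
  volt <- filtfilt_rows(volt, lp, fs, params$lowpass_hz)

  if (params$resample_hz != fs) {
    if (fs %% params$resample_hz == 0) {
      # integer decimation: zero-phase (centered linear-phase FIR) polyphase
      # anti-alias filter just below the new Nyquist, then take every q-th
      # sample
      q <- fs / params$resample_hz
      b <- signal::fir1(64, 0.92 * (params$resample_hz / 2) / (fs / 2))
      rows <- vector("list", nrow(volt))
      for (ch in seq_len(nrow(volt)))
        rows[[ch]] <- cpp_fir_decimate(b, volt[ch, ], q)
      volt <- do.call(rbind, rows)
    } else {
      g <- gcd_int(params$resample_hz, fs)
      rows <- vector("list", nrow(volt))
      for (ch in seq_len(nrow(volt)))
        rows[[ch]] <- signal::resample(volt[ch, ], params$resample_hz / g,
                                       fs / g)
      volt <- do.call(rbind, rows)
    }
  }
  fs_new <- params$resample_hz
  bp <- signal::butter(params$bandpass_order, params$bandpass_hz / (fs_new / 2),
                       type = "pass")
  volt <- filtfilt_rows(volt, bp, fs_new, params$bandpass_hz[1])

  events <- recording$events
  events$sample_index <- pmin(ncol(volt), pmax(1L, as.integer(
    round((events$sample_index - 1) * fs_new / fs) + 1L)))
  structure(list(voltages = volt, sampling_rate_hz = fs_new, events = events,
                 channel_ids = recording$channel_ids,
                 rail_uv = recording$rail_uv),
            class = "session_recording")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Detect signal clipping in a segment
#'
#' A segment is flagged when, on any channel, the absolute voltage stays at
#' or above `clip_threshold * rail` for at least `clip_run_len` consecutive
#' samples.
#'
#' @param segment Channels x samples matrix (or a single-channel vector).
#' @param rail_uv Amplifier rail in the segment's units.
#' @param params A [preproc_params()] carrying the clipping settings.
#' @return Logical flag.
#' @export
detect_clipping <- function(segment, rail_uv, params = preproc_params()) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  if (length(segment) == 0L) stop("empty segment")
  thr <- params$clip_threshold * rail_uv
  for (ch in seq_len(nrow(segment))) {
    r <- rle(abs(segment[ch, ]) >= thr)
    if (any(r$values & r$lengths >= params$clip_run_len)) return(TRUE)
  }
  FALSE
}

#' Flag trials with clipping artifacts
#'
#' Runs [detect_clipping()] on the raw per-trial segment from shortly before
#' sample onset to the end of the post-test window.
#'
#' @param recording Raw (unpreprocessed) `session_recording`.
#' @param records Trial records.
#' @param params A [preproc_params()].
#' @param margin_ms Margin before sample onset / after test onset included in
#'   the check.
#' @return Integer vector of flagged `trial_id`s.
#' @export
flag_clipped_trials <- function(recording, records,
                                params = preproc_params(),
                                margin_ms = c(200, 800)) {
  fs <- recording$sampling_rate_hz
  ev <- recording$events
  flagged <- integer(0)
  for (tid in records$trial_id) {
    s0 <- ev$sample_index[ev$trial_id == tid & ev$label == "sample_on"]
    s1 <- ev$sample_index[ev$trial_id == tid & ev$label == "test_on"]
    if (!length(s0)) next
    if (!length(s1)) s1 <- s0
    lo <- max(1L, s0 - round(margin_ms[1] / 1000 * fs))
    hi <- min(ncol(recording$voltages), s1 + round(margin_ms[2] / 1000 * fs))
    if (detect_clipping(recording$voltages[, lo:hi, drop = FALSE],
                        recording$rail_uv, params))
      flagged <- c(flagged, tid)
  }
  flagged
}

#' Extract event-locked epochs
#'
#' Cuts one epoch per retained trial from a preprocessed recording, locked to
#' the named event. Time-bin timestamps are relative to the locking event
#' (0 ms = event sample) on the half-open window `[window_ms[1],
#' window_ms[2])`, giving `diff(window_ms) / (1000 / fs)` bins. Button
#' presses never truncate epochs.
#'
#' @param recording Preprocessed `session_recording`.
#' @param records Trial records; only trials listed here are considered.
#' @param lock_event `"test_on"` or `"sample_on"`.
#' @param window_ms Length-2 window in ms relative to the event; both ends
#'   must be multiples of the bin width.
#' @param trial_ids Optional subset of trial ids to epoch; defaults to all
#'   trials in `records` that have the locking event.
#' @param exclude Trial ids to drop (e.g. from [flag_clipped_trials()]);
#'   exclusions are reported via a message.
#' @return An object of class `epoched_data`: list with `data` (trials x
#'   channels x time array), `time_ms`, `lock_event`, `trial_ids`,
#'   `channel_ids`, `sampling_rate_hz`.
#' @export
epoch_recording <- function(recording, records,
                            lock_event = c("test_on", "sample_on"),
                            window_ms = c(-200, 600), trial_ids = NULL,
                            exclude = NULL) {
  stopifnot(inherits(recording, "session_recording"))
  lock_event <- match.arg(lock_event)
  fs <- recording$sampling_rate_hz
  dt <- 1000 / fs
  if (any(abs(window_ms / dt - round(window_ms / dt)) > 1e-9))
    stop("window_ms must be multiples of the bin width (", dt, " ms)")
  time_ms <- seq(window_ms[1], window_ms[2] - dt, by = dt)
  offs <- as.integer(round(time_ms / dt))

  ev <- recording$events[recording$events$label == lock_event, ]
  if (is.null(trial_ids))
    trial_ids <- records$trial_id[records$trial_id %in% ev$trial_id]
  if (length(exclude)) {
    dropped <- intersect(trial_ids, exclude)
    if (length(dropped))
      message("epoch_recording: dropping ", length(dropped),
              " excluded trial(s)")
    trial_ids <- setdiff(trial_ids, exclude)
  }
  if (!length(trial_ids)) stop("no trials to epoch")
  pos <- match(trial_ids, ev$trial_id)
  if (anyNA(pos))
    stop("event '", lock_event, "' missing for trial(s) ",
         paste(trial_ids[is.na(pos)], collapse = ", "))
  locks <- ev$sample_index[pos]
  if (any(locks + offs[1] < 1) ||
      any(locks + offs[length(offs)] > ncol(recording$voltages)))
    stop("epoch window exceeds recording bounds")

  n_ch <- nrow(recording$voltages)
  dat <- array(0, dim = c(length(trial_ids), n_ch, length(time_ms)))
  for (i in seq_along(trial_ids))
    dat[i, , ] <- recording$voltages[, locks[i] + offs]
  structure(list(data = dat, time_ms = time_ms, lock_event = lock_event,
                 trial_ids = trial_ids, channel_ids = recording$channel_ids,
                 sampling_rate_hz = fs),
            class = "epoched_data")
}
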