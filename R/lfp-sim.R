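#' Define one injected effect component
#'
#' An effect component is a transient, band-limited waveform added to the
#' synthetic LFP on a defined subset of trials, with a known latency relative
#' to its locking event. Components are the ground truth that downstream
#' decoding is expected to recover.
#'
#' Selectivities:
#' * `color_identity` / `motion_identity`: every presented test carries the
#'   waveform, with a per-feature-level pattern of channel signs, so the four
#'   feature levels are linearly separable from the injected signal.
#' * `color_match` / `motion_match`: the waveform is added only on trials in
#'   which that feature is searched for (present in the sample) and the test
#'   matches it, with one common channel pattern.
#' * `motor_response`: added on button-press trials, locked to the response
#'   event.
#'
#' @param selectivity One of `"color_identity"`, `"motion_identity"`,
#'   `"color_match"`, `"motion_match"`, `"motor_response"`.
#' @param latency_ms Onset latency relative to the locking event (>= 0).
#' @param duration_ms Waveform duration (ms).
#' @param amplitude Peak amplitude (same units as the noise, micro-volts).
#' @param channel_weights Optional per-channel gain vector (length
#'   `n_channels`); defaults to 1 on every channel.
#' @param rise_ms Raised-cosine on/off ramp duration within the waveform.
#' @param cycles Number of sine cycles in the waveform (integer, so the
#'   waveform is exactly zero-mean); its center frequency is
#'   `cycles * 1000 / duration_ms` Hz.
#' @param lock Locking event; defaults to `"response"` for motor components
#'   and `"test_on"` otherwise. `"sample_on"` gives sample-locked components.
#' @param outcomes Optional character vector restricting the component to
#'   trials with these outcomes (e.g. `"correct_rejection"`).
#' @return An object of class `effect_component`.
#' @export
effect_component <- function(selectivity, latency_ms, duration_ms, amplitude,
                             channel_weights = NULL, rise_ms = 40,
                             cycles = 3, lock = NULL, outcomes = NULL) {
  selectivity <- match.arg(selectivity,
    c("color_identity", "motion_identity", "color_match", "motion_match",
      "motor_response"))
  if (latency_ms < 0) stop("latency_ms must be >= 0")
  stopifnot(duration_ms > 0, rise_ms >= 0)
  lock <- lock %||% if (selectivity == "motor_response") "response" else
    "test_on"
  lock <- match.arg(lock, c("test_on", "sample_on", "response"))
  if (selectivity == "motor_response" && lock != "response")
    stop("motor_response components must be locked to the response event")
  if (cycles < 1 || cycles != round(cycles))
    stop("cycles must be a positive integer")
  structure(list(selectivity = selectivity, latency_ms = latency_ms,
                 duration_ms = duration_ms, amplitude = amplitude,
                 channel_weights = channel_weights, rise_ms = rise_ms,
                 cycles = cycles, lock = lock, outcomes = outcomes),
            class = "effect_component")
}

#' Signal model of a synthetic LFP session
#'
#' @param n_channels Number of recording channels (<= 96).
#' @param sampling_rate_hz Native sampling rate of the synthetic recording.
#' @param noise_amp Per-channel 1/f noise standard deviation (micro-volts).
#' @param noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param common_mode_amp Standard deviation of the shared common-mode noise
#'   source added to every channel.
#' @param line_noise_amp Amplitude of the 50 Hz line component.
#' @param evoked Stereotyped stimulus-onset response added at every sample
#'   and test onset on all channels: a list with `amplitude`, `latency_ms`
#'   (peak time) and `width_ms` (full width at half maximum).
#' @param components List of [effect_component()] objects.
#' @param rail_uv Amplifier rail (micro-volts), used by the clipping check.
#' @param pre_sample_ms,post_test_ms Recording time kept before each sample
#'   onset and after each test offset.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(n_channels = 24, sampling_rate_hz = 1000,
                        noise_amp = 10, noise_exponent = 1,
                        common_mode_amp = 3, line_noise_amp = 5,
                        evoked = list(amplitude = 15, latency_ms = 70,
                                      width_ms = 60),
                        components = list(), rail_uv = 500,
                        pre_sample_ms = 300, post_test_ms = 500) {
  stopifnot(n_channels >= 1, n_channels <= 96, sampling_rate_hz > 0,
            noise_amp >= 0, common_mode_amp >= 0, line_noise_amp >= 0)
  for (cmp in components) {
    stopifnot(inherits(cmp, "effect_component"))
    if (!is.null(cmp$channel_weights) &&
        length(cmp$channel_weights) != n_channels)
      stop("channel_weights length must equal n_channels")
  }
  structure(list(n_channels = n_channels,
                 sampling_rate_hz = sampling_rate_hz,
                 noise_amp = noise_amp, noise_exponent = noise_exponent,
                 common_mode_amp = common_mode_amp,
                 line_noise_amp = line_noise_amp, evoked = evoked,
                 components = components, rail_uv = rail_uv,
                 pre_sample_ms = pre_sample_ms, post_test_ms = post_test_ms),
            class = "signal_spec")
}

# 1/f^(beta) power noise synthesized in the frequency domain with random
# phases, normalized to unit standard deviation.
one_over_f_noise <- function(n, exponent) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  if (nfft %% 2L == 1L) nfft <- stats::nextn(nfft + 1L, c(2, 3, 5))
  nf <- nfft %/% 2
  f <- seq_len(nf)
  amp <- 1 / pmax(f, 1)^(exponent / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0 + 0i, spec, Conj(rev(spec[-nf])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

# Transient component waveform: an integer number of sine cycles under a
# raised-cosine (Tukey) window. The sine is antisymmetric about the waveform
# center and the window symmetric, so the waveform has exactly zero mean --
# a multiphasic LFP deflection with its energy near
# cycles * 1000 / duration_ms Hz, well inside the 1-80 Hz analysis band and
# well away from its 1 Hz high-pass edge. That matters: a unipolar bump (or a
# packet with appreciable energy near 1 Hz) acquires long symmetric tails
# from the zero-phase high-pass and would leak effect information far outside
# the waveform's true support, in either temporal direction.
component_envelope <- function(duration_ms, rise_ms, fs, cycles = 3) {
  n <- max(2L, round(duration_ms / 1000 * fs))
  t <- (seq_len(n) - 1) / fs * 1000
  win <- rep(1, n)
  r <- min(rise_ms, duration_ms / 2)
  if (r > 0) {
    up <- t < r
    win[up] <- 0.5 * (1 - cos(pi * t[up] / r))
    dn <- t > duration_ms - r
    win[dn] <- 0.5 * (1 - cos(pi * (duration_ms - t[dn]) / r))
  }
  w <- win * sin(2 * pi * cycles * t / duration_ms)
  w / max(abs(w))
}

# Biphasic evoked kernel (Gaussian derivative; zero mean, peak at latency,
# FWHM of the underlying Gaussian = width), sampled at fs
evoked_kernel <- function(evoked, fs) {
  if (is.null(evoked) || evoked$amplitude == 0) return(numeric(0))
  s <- evoked$width_ms / 2.3548
  t <- seq(0, evoked$latency_ms + 4.5 * s, by = 1000 / fs)
  g <- -(t - evoked$latency_ms - s) / s *
    exp(-0.5 * ((t - evoked$latency_ms - s) / s)^2)
  evoked$amplitude * g / max(abs(g))
}

# linear indices of the (all channels) x (onset..onset+len-1) block, clipped
# at the recording end; used for in-place waveform addition without copying
# the full voltage matrix
patch_block <- function(n_ch, ns, onset, len) {
  if (onset > ns || onset + len - 1L < 1L) return(NULL)
  cols <- onset:min(ns, onset + len - 1L)
  list(cols = cols,
       lin = rep((cols - 1L) * n_ch, each = n_ch) + seq_len(n_ch))
}

# trials on which a component applies, given its selectivity
component_trials <- function(cmp, records) {
  sel <- switch(cmp$selectivity,
    color_identity = ,
    motion_identity = records$outcome != "aborted",
    color_match = records$sample_color != "grey" &
      records$test_color == records$sample_color &
      records$outcome != "aborted",
    motion_match = records$sample_motion != "incoherent" &
      records$test_motion == records$sample_motion &
      records$outcome != "aborted",
    motor_response = !is.na(records$reaction_time_ms))
  if (!is.null(cmp$outcomes)) sel <- sel & records$outcome %in% cmp$outcomes
  which(sel)
}

#' Synthesize a continuous multichannel LFP recording
#'
#' Lays the trial records out on a continuous session timeline and builds
#' `voltages = 1/f noise + common mode + 50 Hz line + evoked responses at
#' every sample/test onset + injected effect components`. Feature-identity
#' components scale a per-feature-level pattern of channel signs; match
#' components are added only where the test matches the searched-for feature;
#' motor components are locked to the response event.
#'
#' @param records Trial records from [simulate_behavior()].
#' @param spec A [signal_spec()].
#' @param config The [task_config()] used to generate the records.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @return A list with `recording` (class `session_recording`: `voltages`
#'   channels x samples matrix in micro-volts, `sampling_rate_hz`, `events`
#'   data.frame with `label`/`sample_index`/`trial_id`, `channel_ids`,
#'   `rail_uv`) and `ground_truth` (class `ground_truth`: the realized
#'   components with per-trial onsets and channel scales, sufficient to
#'   reconstruct the noiseless effect waveforms, plus the master seed).
#' @export
synthesize_lfp <- function(records, spec, config = task_config(), seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"), inherits(config, "task_config"))
  if (any(is.na(records$delay_ms))) stop("trial timing fields incomplete")
  fs <- spec$sampling_rate_hz
  ms2smp <- function(ms) as.integer(round(ms / 1000 * fs))

  n_tr <- nrow(records)
  aborted <- records$outcome == "aborted"
  span_ms <- spec$pre_sample_ms + config$sample_dur_ms +
    ifelse(aborted, records$delay_ms / 2, records$delay_ms +
             config$test_dur_ms + spec$post_test_ms)
  start <- cumsum(c(0, span_ms[-n_tr]))
  sample_on <- ms2smp(start + spec$pre_sample_ms) + 1L
  test_on <- ifelse(aborted, NA_integer_,
                    ms2smp(start + spec$pre_sample_ms +
                             config$sample_dur_ms + records$delay_ms) + 1L)
  resp <- ifelse(is.na(records$reaction_time_ms), NA_integer_,
                 test_on + ms2smp(records$reaction_time_ms))
  ns <- ms2smp(sum(span_ms)) + 1L

  events <- rbind(
    data.frame(label = "sample_on", sample_index = sample_on,
               trial_id = records$trial_id),
    data.frame(label = "test_on", sample_index = test_on,
               trial_id = records$trial_id)[!aborted, ],
    data.frame(label = "response", sample_index = resp,
               trial_id = records$trial_id)[!is.na(resp), ])
  events <- events[order(events$sample_index), ]
  rownames(events) <- NULL
  stopifnot(all(events$sample_index >= 1), all(events$sample_index <= ns))

  withr::with_seed(as.integer(seed), {
    volt <- matrix(0, nrow = spec$n_channels, ncol = ns)
    if (spec$noise_amp > 0)
      for (ch in seq_len(spec$n_channels))
        volt[ch, ] <- spec$noise_amp *
          one_over_f_noise(ns, spec$noise_exponent)
    if (spec$common_mode_amp > 0) {
      cm <- spec$common_mode_amp * one_over_f_noise(ns, spec$noise_exponent)
      volt <- sweep(volt, 2, cm, `+`)
    }
    if (spec$line_noise_amp > 0) {
      ph <- runif(1, 0, 2 * pi)
      tt <- (seq_len(ns) - 1) / fs
      volt <- sweep(volt, 2, spec$line_noise_amp * sin(2 * pi * 50 * tt + ph),
                    `+`)
    }
    kern <- evoked_kernel(spec$evoked, fs)
    if (length(kern)) {
      ones <- rep(1, spec$n_channels)
      for (s in c(sample_on, test_on[!aborted])) {
        blk <- patch_block(spec$n_channels, ns, s, length(kern))
        if (!is.null(blk))
          volt[blk$lin] <- volt[blk$lin] +
            outer(ones, kern[blk$cols - s + 1L])
      }
    }

    realized <- list()
    for (ci in seq_along(spec$components)) {
      cmp <- spec$components[[ci]]
      w <- cmp$channel_weights %||% rep(1, spec$n_channels)
      env <- cmp$amplitude * component_envelope(cmp$duration_ms, cmp$rise_ms,
                                                fs, cmp$cycles)
      idx <- component_trials(cmp, records)
      lock_smp <- switch(cmp$lock, test_on = test_on, sample_on = sample_on,
                         response = resp)
      idx <- idx[!is.na(lock_smp[idx])]
      if (cmp$selectivity %in% c("color_identity", "motion_identity")) {
        feat <- if (cmp$selectivity == "color_identity")
          records$test_color else records$test_motion
        levels_ <- sort(unique(feat[idx]))
        pattern <- matrix(sample(c(-1, 1), length(levels_) * spec$n_channels,
                                 replace = TRUE),
                          nrow = length(levels_),
                          dimnames = list(levels_, NULL))
        scale <- pattern[match(feat[idx], levels_), , drop = FALSE] *
          rep(w, each = length(idx))
      } else {
        scale <- matrix(w, nrow = length(idx), ncol = spec$n_channels,
                        byrow = TRUE)
      }
      onsets <- lock_smp[idx] + ms2smp(cmp$latency_ms)
      over <- onsets + length(env) - 1L > ns
      if (any(over))
        warning("component ", ci, ": waveform clipped at recording end on ",
                sum(over), " trial(s)")
      for (k in seq_along(idx)) {
        blk <- patch_block(spec$n_channels, ns, onsets[k], length(env))
        if (!is.null(blk))
          volt[blk$lin] <- volt[blk$lin] +
            outer(scale[k, ], env[blk$cols - onsets[k] + 1L])
      }
      realized[[ci]] <- list(selectivity = cmp$selectivity,
                             latency_ms = cmp$latency_ms,
                             envelope = env, trial_ids = records$trial_id[idx],
                             onset_sample = onsets, channel_scale = scale)
    }
  })

  recording <- structure(list(voltages = volt, sampling_rate_hz = fs,
                              events = events,
                              channel_ids = seq_len(spec$n_channels),
                              rail_uv = spec$rail_uv),
                         class = "session_recording")
  ground_truth <- structure(list(components = realized, seed = seed,
                                 n_channels = spec$n_channels,
                                 n_samples = ns, sampling_rate_hz = fs),
                            class = "ground_truth")
  list(recording = recording, ground_truth = ground_truth)
}

#' Reconstruct the noiseless injected effect signal
#'
#' Rebuilds, from the ground truth of [synthesize_lfp()], the channels x
#' samples matrix containing only the injected effect components. Subtracting
#' it from the synthesized voltages removes all decodable feature
#' information.
#'
#' @param ground_truth A `ground_truth` object.
#' @return A channels x samples numeric matrix.
#' @export
ground_truth_signal <- function(ground_truth) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  n_ch <- ground_truth$n_channels
  ns <- ground_truth$n_samples
  volt <- matrix(0, n_ch, ns)
  for (cmp in ground_truth$components)
    for (k in seq_along(cmp$trial_ids)) {
      on <- cmp$onset_sample[k]
      blk <- patch_block(n_ch, ns, on, length(cmp$envelope))
      if (!is.null(blk))
        volt[blk$lin] <- volt[blk$lin] +
          outer(cmp$channel_scale[k, ], cmp$envelope[blk$cols - on + 1L])
    }
  volt
}
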