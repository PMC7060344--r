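# Shared builders for the test suite. Validation sessions run at a 500 Hz
# native rate with trimmed inter-trial padding; the methods vignette states
# these scales.

test_signal <- function(n_channels = 24, components = list(), ...) {
  signal_spec(n_channels = n_channels, sampling_rate_hz = 500,
              post_test_ms = 400, components = components, ...)
}

# small, fast session for module-level tests: one task, 8 channels
tiny_config <- function(analysis = "feature_decoding", feature = "color",
                        task = "color", components = list(), seed = 1,
                        n_repeats = 3, n_perm = 10,
                        window_ms = c(-40, 140), n_channels = 8, ...) {
  analysis_config(
    analysis = analysis, feature = feature, task = task,
    task_cfg = task_config(task_types = task),
    signal = test_signal(n_channels = n_channels, components = components),
    n_repeats = n_repeats, n_perm = n_perm, seed = seed,
    window_ms = window_ms, ...)
}

# hand-built inference objects with known statistics
fake_tc <- function(acc, time_ms, n_classes = 2) {
  structure(list(time_ms = time_ms, accuracy = acc,
                 mean_accuracy = colMeans(acc), n_classes = n_classes,
                 chance = 1 / n_classes, retained = seq_len(10),
                 spec = decoder_spec(), seed = 1L,
                 class_names = paste0("c", seq_len(n_classes))),
            class = "decoding_timecourse")
}

fake_null <- function(mat, time_ms, n_classes = 2) {
  structure(list(accuracies = mat, time_ms = time_ms, n_perm = nrow(mat),
                 n_classes = n_classes, chance = 1 / n_classes, seed = 1L),
            class = "null_ensemble")
}

# epochs filled by a caller-supplied function of (trial, channel, bin)
fake_epochs <- function(n_trials, n_channels, n_bins, fill, dt = 4) {
  dat <- array(fill, dim = c(n_trials, n_channels, n_bins))
  structure(list(data = dat, time_ms = seq(0, by = dt, length.out = n_bins),
                 lock_event = "test_on", trial_ids = seq_len(n_trials),
                 channel_ids = seq_len(n_channels), sampling_rate_hz = 250),
            class = "epoched_data")
}

expect_binomial_band <- function(acc, chance, n, level = 0.99) {
  half <- qnorm(1 - (1 - level) / 2) * sqrt(chance * (1 - chance) / n)
  expect_true(all(acc >= chance - half & acc <= chance + half))
}
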