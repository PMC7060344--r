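mk_rec <- function(x, fs = 1000, trial_id = 1L) {
  v <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(voltages = v, sampling_rate_hz = fs,
                 events = data.frame(label = "test_on",
                                     sample_index = as.integer(ncol(v) / 2),
                                     trial_id = trial_id),
                 channel_ids = seq_len(nrow(v)), rail_uv = 500),
            class = "session_recording")
}

test_that("a 50 Hz sinusoid is attenuated by at least 20 dB", {
  fs <- 1000; n <- 20000
  s <- sin(2 * pi * 50 * (seq_len(n) - 1) / fs)
  out <- preprocess_continuous(mk_rec(s))$voltages[1, ]
  i <- 200:(length(out) - 200)
  atten <- 20 * log10(sqrt(mean(out[i]^2)) / sqrt(0.5))
  expect_lt(atten, -20)
})

test_that("DC is removed and in-band signals pass unchanged", {
  fs <- 1000; n <- 20000
  out <- preprocess_continuous(mk_rec(rep(5, n)))$voltages[1, ]
  i <- 500:(length(out) - 500)
  expect_lt(sqrt(mean(out[i]^2)), 0.05)
  s10 <- sin(2 * pi * 10 * (seq_len(n) - 1) / fs)
  o10 <- preprocess_continuous(mk_rec(s10))$voltages[1, ]
  expect_lt(abs(sqrt(mean(o10[i]^2)) / sqrt(0.5) - 1), 0.01)
})

test_that("resampling length arithmetic and event remapping are exact", {
  out <- preprocess_continuous(mk_rec(rnorm(4000)))
  expect_equal(ncol(out$voltages), 1000L)
  expect_equal(out$sampling_rate_hz, 250)
  # relative event latencies preserved within one output sample
  rec <- mk_rec(rnorm(8000))
  rec$events <- data.frame(label = c("sample_on", "test_on"),
                           sample_index = c(1001L, 3501L), trial_id = 1L)
  out2 <- preprocess_continuous(rec)
  lat_in <- diff(rec$events$sample_index) / 1000
  lat_out <- diff(out2$events$sample_index) / 250
  expect_lt(abs(lat_out - lat_in), 1 / 250 + 1e-12)
})

test_that("the chain is near-idempotent on band-limited resampled data", {
  fs <- 250; n <- 5000
  s <- sin(2 * pi * 12 * (seq_len(n) - 1) / fs)
  p <- preproc_params(lowpass_hz = 100, resample_hz = 250)
  once <- preprocess_continuous(mk_rec(s, fs = fs), p)
  twice <- preprocess_continuous(once, p)
  i <- 300:(n - 300)
  expect_lt(max(abs(once$voltages[1, i] - twice$voltages[1, i])), 0.02)
})

test_that("rate preconditions are enforced", {
  expect_error(preprocess_continuous(mk_rec(rnorm(100), fs = 250)),
               "native rate")
  expect_error(preproc_params(bandpass_hz = c(1, 160)), "low-pass")
  expect_error(preproc_params(bandpass_hz = c(1, 130), lowpass_hz = 140),
               "Nyquist")
})

test_that("clipping detection follows the run-length rule", {
  p <- preproc_params(clip_run_len = 10)
  seg <- rnorm(500, sd = 10)
  seg[101:150] <- 500                       # pinned at rail for 50 samples
  expect_true(detect_clipping(seg, 500, p))
  expect_false(detect_clipping(rnorm(500, sd = 10), 500, p))
  spike <- rnorm(500, sd = 10)
  spike[200] <- 500                         # single-sample spike
  expect_false(detect_clipping(spike, 500, preproc_params(clip_run_len = 3)))
  expect_error(detect_clipping(numeric(0), 500), "empty")
})

test_that("epoching yields the documented bin count and never truncates at responses", {
  cfgc <- task_config(task_types = "color")
  pool <- build_trial_pool(cfgc, 1)
  rec <- simulate_behavior(pool, behavior_params(abort_rate = 0), cfgc,
                           seed = 31)
  sim <- synthesize_lfp(rec, test_signal(n_channels = 2), cfgc, seed = 1)
  pre <- preprocess_continuous(sim$recording)
  ep <- epoch_recording(pre, rec, "test_on", c(-200, 600))
  expect_equal(dim(ep$data)[3], 200L)       # 800 ms / 4 ms
  expect_equal(diff(ep$time_ms)[1], 4)
  # a trial with an early press still spans the full window and matches the
  # continuous recording sample-for-sample
  pressed <- rec$trial_id[!is.na(rec$reaction_time_ms)][1]
  i <- match(pressed, ep$trial_ids)
  lock <- pre$events$sample_index[pre$events$label == "test_on" &
                                    pre$events$trial_id == pressed]
  expect_equal(ep$data[i, , ],
               pre$voltages[, lock + as.integer(ep$time_ms / 4)])
})

test_that("excluded trials are dropped from epochs with a message", {
  cfgc <- task_config(task_types = "color")
  pool <- build_trial_pool(cfgc, 1)
  rec <- simulate_behavior(pool, behavior_params(abort_rate = 0), cfgc,
                           seed = 32)
  sim <- synthesize_lfp(rec, test_signal(n_channels = 2), cfgc, seed = 2)
  pre <- preprocess_continuous(sim$recording)
  expect_message(
    ep <- epoch_recording(pre, rec, "test_on", c(-100, 300),
                          exclude = rec$trial_id[1:2]),
    "excluded")
  expect_false(any(rec$trial_id[1:2] %in% ep$trial_ids))
  expect_error(epoch_recording(pre, rec, "test_on", c(-100, 300),
                               trial_ids = 99999), "missing")
  expect_error(epoch_recording(pre, rec, "test_on", c(-1e5, 300)),
               "bounds")
})

test_that("a clipped synthetic trial is flagged", {
  cfgc <- task_config(task_types = "color")
  rec <- simulate_behavior(build_trial_pool(cfgc, 1),
                           behavior_params(abort_rate = 0), cfgc, seed = 33)
  sim <- synthesize_lfp(rec, test_signal(n_channels = 2), cfgc, seed = 3)
  ev <- sim$recording$events
  t1 <- ev$sample_index[ev$label == "test_on" & ev$trial_id == rec$trial_id[5]]
  sim$recording$voltages[1, t1:(t1 + 30)] <- 500   # pin at the rail
  flagged <- flag_clipped_trials(sim$recording, rec)
  expect_true(rec$trial_id[5] %in% flagged)
})

test_that("session recordings round-trip through serialization", {
  cfgc <- task_config(task_types = "color")
  rec <- simulate_behavior(build_trial_pool(cfgc, 1),
                           behavior_params(), cfgc, seed = 34)
  sim <- synthesize_lfp(rec, test_signal(n_channels = 2), cfgc, seed = 4)
  f <- tempfile(fileext = ".rds")
  write_session_recording(sim$recording, f)
  back <- read_session_recording(f)
  expect_identical(back$voltages, sim$recording$voltages)
  ft <- tempfile(fileext = ".csv")
  write_trial_records(rec, ft)
  back2 <- read_trial_records(ft)
  expect_equal(back2$outcome, rec$outcome)
  expect_equal(back2$reaction_time_ms, rec$reaction_time_ms, tolerance = 1e-9)
})
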