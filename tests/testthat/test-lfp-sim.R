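cfg_color <- task_config(task_types = "color")
pool_small <- build_trial_pool(cfg_color, 2)
rec_small <- simulate_behavior(pool_small, behavior_params(), cfg_color,
                               seed = 11)

test_that("event lists are complete and consistent with the trial records", {
  sim <- synthesize_lfp(rec_small, test_signal(n_channels = 4), cfg_color,
                        seed = 1)
  ev <- sim$recording$events
  ns <- ncol(sim$recording$voltages)
  expect_true(all(ev$sample_index >= 1 & ev$sample_index <= ns))
  live <- rec_small$trial_id[rec_small$outcome != "aborted"]
  expect_setequal(ev$trial_id[ev$label == "test_on"], live)
  expect_setequal(ev$trial_id[ev$label == "sample_on"], rec_small$trial_id)
  pressed <- rec_small$trial_id[!is.na(rec_small$reaction_time_ms)]
  expect_setequal(ev$trial_id[ev$label == "response"], pressed)
  # response latency encoded in samples matches the recorded RT
  fs <- sim$recording$sampling_rate_hz
  for (tid in head(pressed, 5)) {
    t_on <- ev$sample_index[ev$label == "test_on" & ev$trial_id == tid]
    resp <- ev$sample_index[ev$label == "response" & ev$trial_id == tid]
    rt <- rec_small$reaction_time_ms[rec_small$trial_id == tid]
    expect_lt(abs((resp - t_on) / fs * 1000 - rt), 1000 / fs + 1e-9)
  }
})

test_that("identical seed and inputs give bit-identical recordings", {
  a <- synthesize_lfp(rec_small, test_signal(n_channels = 3), cfg_color,
                      seed = 9)
  b <- synthesize_lfp(rec_small, test_signal(n_channels = 3), cfg_color,
                      seed = 9)
  expect_identical(a$recording$voltages, b$recording$voltages)
  expect_identical(a$recording$events, b$recording$events)
  expect_identical(a$ground_truth$components, b$ground_truth$components)
})

test_that("a noiseless identity component separates feature levels only after its latency", {
  spec <- signal_spec(n_channels = 4, sampling_rate_hz = 500,
                      noise_amp = 0, common_mode_amp = 0, line_noise_amp = 0,
                      evoked = NULL, post_test_ms = 400,
                      components = list(
                        effect_component("color_identity", latency_ms = 100,
                                         duration_ms = 120, amplitude = 10)))
  sim <- synthesize_lfp(rec_small, spec, cfg_color, seed = 2)
  ep <- epoch_recording(sim$recording, rec_small, "test_on", c(-100, 300))
  r <- rec_small[match(ep$trial_ids, rec_small$trial_id), ]
  spread <- sapply(seq_along(ep$time_ms), function(b) {
    mu <- tapply(ep$data[, 1, b], r$test_color, mean)
    diff(range(mu))
  })
  expect_true(all(spread[ep$time_ms < 100] == 0))
  expect_gt(max(spread[ep$time_ms >= 100]), 1)
})

test_that("subtracting the ground-truth waveforms removes all decodable structure", {
  comp <- effect_component("color_identity", latency_ms = 60,
                           duration_ms = 120, amplitude = 60)
  cfg <- tiny_config(components = list(comp), seed = 21, n_repeats = 4)
  seeds <- mtsdecode:::derive_seeds(cfg$seed, 5L)
  records <- simulate_behavior(build_trial_pool(cfg$task_cfg, cfg$n_repeats),
                               cfg$behavior, cfg$task_cfg, seed = seeds[1])
  sim <- synthesize_lfp(records, cfg$signal, cfg$task_cfg, seed = seeds[2])
  sim$recording$voltages <- sim$recording$voltages -
    ground_truth_signal(sim$ground_truth)
  pre <- preprocess_continuous(sim$recording, cfg$preproc)
  keep <- records$trial_id[records$outcome %in% c("hit", "correct_rejection")]
  ep <- epoch_recording(pre, records, "test_on", cfg$window_ms,
                        trial_ids = keep)
  r <- records[match(ep$trial_ids, records$trial_id), ]
  ds <- labeled_dataset(ep, factor(r$test_color))
  tc <- decode_timecourse(ds, decoder_spec(), seed = 5)
  n_eval <- length(tc$retained)
  expect_binomial_band(tc$mean_accuracy, tc$chance, n_eval, level = 0.999)
})

test_that("pure-noise sessions decode at chance", {
  cfg <- tiny_config(seed = 22, n_repeats = 4)
  res_session <- simulate_session(cfg)
  sel <- select_trials(res_session$records, cfg)
  keep <- sel$trial_ids %in% res_session$epochs$trial_ids
  rows <- match(sel$trial_ids[keep], res_session$epochs$trial_ids)
  ep <- res_session$epochs
  ep$data <- ep$data[rows, , , drop = FALSE]
  ep$trial_ids <- ep$trial_ids[rows]
  ds <- labeled_dataset(ep, droplevels(sel$labels[keep]))
  tc <- decode_timecourse(ds, decoder_spec(), seed = 1)
  expect_binomial_band(tc$mean_accuracy, tc$chance, length(tc$retained),
                       level = 0.999)
})

test_that("component restrictions and validation behave as specified", {
  expect_error(effect_component("color_identity", -1, 100, 1), "latency")
  expect_error(effect_component("motor_response", 0, 100, 1,
                                lock = "test_on"), "response event")
  expect_error(signal_spec(n_channels = 4, components = list(
    effect_component("color_match", 50, 100, 1,
                     channel_weights = rep(1, 7)))), "channel_weights")
  # waveform overrunning the recording end warns and clips
  rec1 <- rec_small[1:3, ]
  rec1$delay_ms <- 800
  spec <- test_signal(n_channels = 2, components = list(
    effect_component("color_identity", latency_ms = 0, duration_ms = 60000,
                     amplitude = 1)))
  expect_warning(synthesize_lfp(rec1, spec, cfg_color, seed = 1), "clipped")
})

test_that("match components land only on searched-feature matches", {
  cfg_conj <- task_config(task_types = "conjunction")
  pool <- build_trial_pool(cfg_conj, 1)
  rec <- simulate_behavior(pool, behavior_params(abort_rate = 0), cfg_conj,
                           seed = 3)
  spec <- test_signal(n_channels = 2, components = list(
    effect_component("color_match", latency_ms = 50, duration_ms = 100,
                     amplitude = 5)))
  sim <- synthesize_lfp(rec, spec, cfg_conj, seed = 4)
  gt_ids <- sim$ground_truth$components[[1]]$trial_ids
  expected <- rec$trial_id[rec$test_color == rec$sample_color &
                             rec$outcome != "aborted"]
  expect_setequal(gt_ids, expected)
  # outcome restriction narrows the carrier set
  spec2 <- test_signal(n_channels = 2, components = list(
    effect_component("color_match", latency_ms = 50, duration_ms = 100,
                     amplitude = 5, outcomes = "correct_rejection")))
  sim2 <- synthesize_lfp(rec, spec2, cfg_conj, seed = 4)
  expect_true(all(rec$outcome[match(sim2$ground_truth$components[[1]]$trial_ids,
                                    rec$trial_id)] == "correct_rejection"))
})
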