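#' Analysis configuration
#'
#' Bundles every stage's parameters for a config-driven end-to-end run. Three
#' analysis designs are available:
#' * `feature_decoding`: labels are the test stimulus color (or motion),
#'   among correct trials, optionally restricted to one task rule; balanced
#'   over the other test feature and the outcome.
#' * `outcome_decoding`: labels are two outcome classes (hit vs correct
#'   rejection by default); trials with reaction times below `min_rt_ms` are
#'   excluded; balanced over both test features. Choosing
#'   `outcome_classes = c("false_alarm", "correct_rejection")` gives the
#'   motor-outcome control on non-target trials only, balanced over the
#'   mismatch type (match status) instead of stimulus identity, so that a
#'   stimulus-locked match signal cannot masquerade as motor information.
#' * `match_decoding`: conjunction-task correct rejections only; labels are
#'   half-matching tests (the test matches the searched-for color, or motion,
#'   but not both) vs complete mismatches; balanced over both test features.
#'
#' @param analysis One of `"feature_decoding"`, `"outcome_decoding"`,
#'   `"match_decoding"`.
#' @param outcome_classes For `outcome_decoding`: the two outcome labels to
#'   separate.
#' @param feature For feature/match decoding: `"color"` or `"motion"`.
#' @param task Task rule to analyze (`"color"`, `"motion"`, `"conjunction"`,
#'   or `"all"`); `match_decoding` is always conjunction-only.
#' @param lock_event Event to which epochs are locked.
#' @param window_ms Epoch window (ms, relative to the locking event).
#' @param task_cfg,behavior,signal,preproc,decoder Stage parameter objects
#'   (see [task_config()], [behavior_params()], [signal_spec()],
#'   [preproc_params()], [decoder_spec()]).
#' @param n_repeats Trial pool repeats for the simulation.
#' @param n_perm Permutation runs for the null ensemble.
#' @param alpha Per-bin significance threshold for decoding.
#' @param contrast_alpha Bonferroni-corrected alpha for condition contrasts.
#' @param onset_window_ms Sustained-significance window for onsets.
#' @param min_rt_ms Reaction-time exclusion floor for analyses containing
#'   button presses.
#' @param seed Master seed; every stage draws its own substream from it.
#' @param session_id Identifier for the simulated session.
#' @param out_dir Optional output directory for summary CSVs.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(analysis = c("feature_decoding",
                                         "outcome_decoding",
                                         "match_decoding"),
                            feature = c("color", "motion"),
                            outcome_classes = c("hit", "correct_rejection"),
                            task = "all",
                            lock_event = "test_on",
                            window_ms = c(-100, 300),
                            task_cfg = task_config(),
                            behavior = behavior_params(),
                            signal = signal_spec(),
                            preproc = preproc_params(),
                            decoder = decoder_spec(),
                            n_repeats = 2, n_perm = 500, alpha = 1e-4,
                            contrast_alpha = 0.05 / 3, onset_window_ms = 40,
                            min_rt_ms = 300, seed = 1L, session_id = "S1",
                            out_dir = NULL) {
  analysis <- match.arg(analysis)
  feature <- match.arg(feature)
  outcome_classes <- match.arg(outcome_classes,
    c("hit", "miss", "false_alarm", "correct_rejection"), several.ok = TRUE)
  if (length(outcome_classes) != 2L)
    stop("outcome_classes must name exactly two outcomes")
  task <- match.arg(task, c("all", "color", "motion", "conjunction"))
  if (analysis == "match_decoding") task <- "conjunction"
  stopifnot(inherits(task_cfg, "task_config"),
            inherits(behavior, "behavior_params"),
            inherits(signal, "signal_spec"),
            inherits(preproc, "preproc_params"),
            inherits(decoder, "decoder_spec"),
            length(window_ms) == 2L, window_ms[1] < window_ms[2],
            n_perm >= 2, alpha > 0, alpha <= 1)
  structure(list(analysis = analysis, feature = feature,
                 outcome_classes = outcome_classes, task = task,
                 lock_event = lock_event, window_ms = window_ms,
                 task_cfg = task_cfg, behavior = behavior, signal = signal,
                 preproc = preproc, decoder = decoder,
                 n_repeats = n_repeats, n_perm = n_perm, alpha = alpha,
                 contrast_alpha = contrast_alpha,
                 onset_window_ms = onset_window_ms, min_rt_ms = min_rt_ms,
                 seed = as.integer(seed), session_id = session_id,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Scalar fields map directly onto [analysis_config()] arguments; the nested
#' mappings `task_cfg`, `behavior`, `signal`, `preproc` and `decoder` are
#' passed to the corresponding constructors. Signal components are given as a
#' list of mappings with [effect_component()] fields.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  ctors <- list(task_cfg = task_config, behavior = behavior_params,
                preproc = preproc_params, decoder = decoder_spec)
  for (nm in names(ctors))
    if (!is.null(y[[nm]])) args[[nm]] <- do.call(ctors[[nm]], y[[nm]])
  if (!is.null(y$signal)) {
    sig <- y$signal
    comps <- lapply(sig$components, function(cc)
      do.call(effect_component, cc))
    sig$components <- NULL
    obj <- do.call(signal_spec, sig)
    obj$components <- comps
    args$signal <- obj
  }
  do.call(analysis_config, args)
}

#' Simulate a complete session for a configured analysis
#'
#' Runs trial-pool construction, behavioral simulation, LFP synthesis,
#' preprocessing, the clipping check and epoching, using substream seeds
#' derived from the master seed.
#'
#' @param config An [analysis_config()].
#' @return List with `records`, `epochs`, `ground_truth`, `clipped`
#'   (flagged trial ids) and `seeds` (the substream seeds used).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- derive_seeds(config$seed, 5L)
  pool <- build_trial_pool(config$task_cfg, config$n_repeats)
  records <- simulate_behavior(pool, config$behavior, config$task_cfg,
                               seed = seeds[1],
                               session_id = config$session_id)
  sim <- synthesize_lfp(records, config$signal, config$task_cfg,
                        seed = seeds[2])
  clipped <- flag_clipped_trials(sim$recording, records, config$preproc)
  pre <- preprocess_continuous(sim$recording, config$preproc)
  has_test <- records$trial_id[records$outcome != "aborted"]
  epochs <- epoch_recording(pre, records, config$lock_event,
                            config$window_ms,
                            trial_ids = setdiff(has_test, clipped))
  list(records = records, epochs = epochs, ground_truth = sim$ground_truth,
       clipped = clipped, seeds = seeds)
}

#' Select trials, labels and balance covariates for an analysis design
#'
#' @param records Trial records.
#' @param config An [analysis_config()].
#' @return List with `trial_ids`, `labels` (factor) and `covariates`
#'   (data.frame).
#' @export
select_trials <- function(records, config) {
  r <- records
  if (config$task != "all") r <- r[r$task_type == config$task, ]
  if (config$analysis == "feature_decoding") {
    r <- r[r$outcome %in% c("hit", "correct_rejection"), ]
    labels <- if (config$feature == "color") r$test_color else r$test_motion
    covariates <- data.frame(
      other = if (config$feature == "color") r$test_motion else r$test_color,
      outcome = r$outcome)
  } else if (config$analysis == "outcome_decoding") {
    cls <- config$outcome_classes
    r <- r[r$outcome %in% cls, ]
    r <- r[is.na(r$reaction_time_ms) |
             r$reaction_time_ms >= config$min_rt_ms, ]
    labels <- r$outcome
    if (setequal(cls, c("false_alarm", "correct_rejection"))) {
      # press vs no-press among non-targets: balance the match status so a
      # stimulus-locked match signal cannot stand in for motor information
      r2 <- r[!r$is_target, ]
      labels <- r2$outcome
      covariates <- data.frame(mismatch_type = r2$mismatch_type)
      r <- r2
    } else {
      covariates <- data.frame(test_color = r$test_color,
                               test_motion = r$test_motion)
    }
  } else {  # match_decoding
    # half-matching tests share the searched-for `feature` with the sample,
    # i.e. only the *other* feature mismatches
    half <- if (config$feature == "color") "motion" else "color"
    r <- r[r$task_type == "conjunction" &
             r$outcome == "correct_rejection" &
             r$mismatch_type %in% c(half, "complete"), ]
    if (nrow(r) == 0L)
      stop("match_decoding: no conjunction correct-rejection trials with ",
           "mismatch type '", half, "' or 'complete'")
    labels <- ifelse(r$mismatch_type == "complete", "complete_mismatch",
                     paste0(config$feature, "_half_match"))
    covariates <- data.frame(test_color = r$test_color,
                             test_motion = r$test_motion)
  }
  if (config$task == "all" && config$analysis != "match_decoding")
    covariates$task <- r$task_type
  list(trial_ids = r$trial_id, labels = factor(labels),
       covariates = covariates)
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes simulate (or ingest) -> preprocess -> epoch -> select/balance ->
#' decode -> permutation null -> significance -> onset -> per-fold onsets,
#' and optionally writes summary CSVs. Identical configuration and master
#' seed give byte-identical outputs.
#'
#' @param config An [analysis_config()].
#' @param session Optional precomputed session from [simulate_session()]
#'   (reused, e.g., to run several analyses on one simulated session);
#'   simulated from the config when `NULL`.
#' @return A results bundle (class `pipeline_result`): `config`, `records`,
#'   `dataset`, `timecourse`, `null`, `trace`, `onset`, `fold_onsets`,
#'   `ground_truth`, `clipped`.
#' @export
run_pipeline <- function(config, session = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(session)) session <- simulate_session(config)
  seeds <- derive_seeds(config$seed + 1L, 2L)
  sel <- select_trials(session$records, config)
  keep <- sel$trial_ids %in% session$epochs$trial_ids
  if (!any(keep)) stop("no selected trials with usable epochs")
  rows <- match(sel$trial_ids[keep], session$epochs$trial_ids)
  ep <- session$epochs
  ep$data <- ep$data[rows, , , drop = FALSE]
  ep$trial_ids <- ep$trial_ids[rows]
  dataset <- labeled_dataset(ep, droplevels(sel$labels[keep]),
                             sel$covariates[keep, , drop = FALSE])
  tc <- decode_timecourse(dataset, config$decoder, seed = seeds[1])
  null <- permutation_null(dataset, config$decoder, n_perm = config$n_perm,
                           seed = seeds[2])
  trace <- significance_trace(tc, null, alpha = config$alpha)
  onset <- detect_onset(trace, window_ms = config$onset_window_ms)
  fo <- fold_onsets(tc, null, alpha = config$alpha,
                    window_ms = config$onset_window_ms)
  res <- structure(list(config = config, records = session$records,
                        dataset = dataset, timecourse = tc, null = null,
                        trace = trace, onset = onset, fold_onsets = fo,
                        ground_truth = session$ground_truth,
                        clipped = session$clipped),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' Write the summary CSVs of a pipeline result
#'
#' Writes `trials.csv` (trial metadata), `timecourse.csv` (per-bin mean
#' accuracy, null mean/sd, z, p, significance) and `onsets.csv` (analysis
#' label, onset, per-fold onsets) into `dir`.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  label <- paste(cfg$analysis, cfg$feature, cfg$task, sep = "_")
  p1 <- file.path(dir, "trials.csv")
  write.csv(result$records, p1, row.names = FALSE)
  tcdf <- data.frame(time_ms = result$timecourse$time_ms,
                     mean_accuracy = result$timecourse$mean_accuracy,
                     null_mean = colMeans(result$null$accuracies),
                     null_sd = apply(result$null$accuracies, 2, sd),
                     z = result$trace$z, p = result$trace$p,
                     significant = result$trace$significant)
  p2 <- file.path(dir, "timecourse.csv")
  write.csv(tcdf, p2, row.names = FALSE)
  ons <- data.frame(analysis = label, seed = cfg$seed,
                    n_classes = result$timecourse$n_classes,
                    n_trials = length(result$timecourse$retained),
                    onset_ms = result$onset$onset_ms,
                    n_significant_bins = sum(result$trace$significant),
                    fold = seq_along(result$fold_onsets),
                    fold_onset_ms = as.numeric(result$fold_onsets))
  p3 <- file.path(dir, "onsets.csv")
  write.csv(ons, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
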