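#' Task configuration for a delayed match-to-sample session
#'
#' Describes the three interleaved task rules (color, motion, conjunction
#' matching), the stimulus feature sets and their pairing into opposed
#' feature pairs, and the trial epoch timing. Colors and motion directions
#' are partitioned into two opposed pairs each, so that a non-matching test
#' feature is always the "opposite" member of the sample feature's pair and
#' the target likelihood within every task type is exactly 1/2.
#'
#' @param colors Character vector of the four test stimulus colors.
#' @param motions Character vector of the four cardinal motion directions.
#' @param color_pairs,motion_pairs Lists of two character vectors of length
#'   two partitioning the feature sets into opposed pairs.
#' @param sample_dur_ms Sample presentation duration (ms).
#' @param delay_range_ms Length-2 numeric; the memory delay is drawn
#'   uniformly from this interval (ms).
#' @param test_dur_ms Test presentation duration (ms).
#' @param response_window_ms Maximum accepted button-press latency after
#'   test onset (ms); later presses count as no-response.
#' @param task_types Character vector of task rules to include.
#' @return An object of class `task_config`.
#' @export
task_config <- function(colors = c("orange", "cyan", "green", "magenta"),
                        motions = c("up", "down", "left", "right"),
                        color_pairs = list(c("orange", "cyan"),
                                           c("green", "magenta")),
                        motion_pairs = list(c("up", "down"),
                                            c("left", "right")),
                        sample_dur_ms = 1000,
                        delay_range_ms = c(800, 1600),
                        test_dur_ms = 250,
                        response_window_ms = 600,
                        task_types = c("color", "motion", "conjunction")) {
  stopifnot(length(colors) == 4L, length(motions) == 4L,
            length(delay_range_ms) == 2L,
            delay_range_ms[1] <= delay_range_ms[2],
            sample_dur_ms > 0, test_dur_ms > 0, response_window_ms > 0)
  if (!setequal(unlist(color_pairs), colors) ||
      anyDuplicated(unlist(color_pairs)))
    stop("color_pairs must partition the color set exactly")
  if (!setequal(unlist(motion_pairs), motions) ||
      anyDuplicated(unlist(motion_pairs)))
    stop("motion_pairs must partition the motion set exactly")
  task_types <- match.arg(task_types,
                          c("color", "motion", "conjunction"),
                          several.ok = TRUE)
  structure(list(colors = colors, motions = motions,
                 color_pairs = color_pairs, motion_pairs = motion_pairs,
                 sample_dur_ms = sample_dur_ms,
                 delay_range_ms = delay_range_ms,
                 test_dur_ms = test_dur_ms,
                 response_window_ms = response_window_ms,
                 task_types = task_types),
            class = "task_config")
}

opposite_feature <- function(feature, pairs) {
  for (p in pairs) {
    if (feature == p[1]) return(p[2])
    if (feature == p[2]) return(p[1])
  }
  stop("feature '", feature, "' not found in pairs")
}

#' Build the balanced trial pool of a session
#'
#' Enumerates every possible stimulus configuration within each task type and
#' replicates it `n_repeats` times. In the single-feature tasks the test
#' either matches the sample's relevant feature or carries the opposite
#' feature, while the irrelevant feature takes all four values, so half of
#' all entries are targets. In the conjunction task the test can mismatch the
#' sample in color only, motion only, or both; each full-match configuration
#' enters the pool three times so that the three mismatch types are jointly
#' as frequent as full matches and the target likelihood is exactly 1/2.
#'
#' @param config A [task_config()].
#' @param n_repeats Number of copies of each configuration (conjunction full
#'   matches get `3 * n_repeats`, see above). Must be >= 1.
#' @return A data.frame with one row per pool entry: `pool_id`, `task_type`,
#'   `sample_color`, `sample_motion`, `test_color`, `test_motion`,
#'   `is_target`, `mismatch_type` (one of `"match"`, `"color"`, `"motion"`,
#'   `"complete"`, naming the features in which the test differs from the
#'   sample).
#' @export
build_trial_pool <- function(config, n_repeats = 1) {
  stopifnot(inherits(config, "task_config"))
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1)
    stop("n_repeats must be a count >= 1")
  n_repeats <- as.integer(n_repeats)
  rows <- list()
  add <- function(task, sc, sm, tc, tm, times = n_repeats) {
    target <- switch(task,
      color = tc == sc,
      motion = tm == sm,
      conjunction = tc == sc && tm == sm)
    diff_c <- !identical(tc, sc) && sc != "grey"
    diff_m <- !identical(tm, sm) && sm != "incoherent"
    mm <- if (!diff_c && !diff_m) "match"
          else if (diff_c && diff_m) "complete"
          else if (diff_c) "color" else "motion"
    rows[[length(rows) + 1L]] <<- data.frame(
      task_type = task, sample_color = sc, sample_motion = sm,
      test_color = tc, test_motion = tm, is_target = target,
      mismatch_type = mm, n = times, stringsAsFactors = FALSE)
  }
  if ("color" %in% config$task_types) {
    for (sc in config$colors)
      for (tc in c(sc, opposite_feature(sc, config$color_pairs)))
        for (tm in config$motions)
          add("color", sc, "incoherent", tc, tm)
  }
  if ("motion" %in% config$task_types) {
    for (sm in config$motions)
      for (tm in c(sm, opposite_feature(sm, config$motion_pairs)))
        for (tc in config$colors)
          add("motion", "grey", sm, tc, tm)
  }
  if ("conjunction" %in% config$task_types) {
    for (sc in config$colors)
      for (sm in config$motions) {
        oc <- opposite_feature(sc, config$color_pairs)
        om <- opposite_feature(sm, config$motion_pairs)
        add("conjunction", sc, sm, sc, sm, times = 3L * n_repeats)
        add("conjunction", sc, sm, oc, sm)   # color-only mismatch
        add("conjunction", sc, sm, sc, om)   # motion-only mismatch
        add("conjunction", sc, sm, oc, om)   # complete mismatch
      }
  }
  pool <- do.call(rbind, rows)
  pool <- pool[rep(seq_len(nrow(pool)), pool$n), , drop = FALSE]
  pool$n <- NULL
  pool$pool_id <- seq_len(nrow(pool))
  rownames(pool) <- NULL
  # target probability must be exactly 1/2 within every task type
  for (tt in unique(pool$task_type)) {
    tf <- mean(pool$is_target[pool$task_type == tt])
    if (abs(tf - 0.5) > 1e-12)
      stop("internal error: target fraction ", tf, " in task ", tt)
  }
  pool[, c("pool_id", "task_type", "sample_color", "sample_motion",
           "test_color", "test_motion", "is_target", "mismatch_type")]
}
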