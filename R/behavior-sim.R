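#' Parameters of the simulated signal-detection observer
#'
#' The synthetic observer is an equal-variance Gaussian signal-detection
#' model. On every trial it draws, for each task-relevant feature, a match
#' evidence value from N(d', 1) when the test matches the sample in that
#' feature and from N(0, 1) otherwise, and presses the button when the
#' decision variable exceeds the response criterion. In conjunction trials
#' the decision variable is the minimum of the two feature evidences (both
#' features must match for a target), which reproduces the characteristic
#' drop in sensitivity for single-feature mismatches. Reaction times follow a
#' shifted log-normal distribution; presses later than the response window
#' count as no-response.
#'
#' @param dprime_color,dprime_motion Sensitivity (d' scale) of the color and
#'   motion match evidence. `Inf` yields a perfect observer for that feature.
#' @param criterion Response criterion on the evidence scale.
#' @param lapse_rate Probability of replacing the decision by a random
#'   guess (in `[0, 1)`).
#' @param rt_shift_ms,rt_meanlog,rt_sdlog Shifted log-normal reaction time
#'   parameters: `rt = rt_shift_ms + rlnorm(rt_meanlog, rt_sdlog)` (ms).
#' @param abort_rate Probability that a trial is aborted (fixation break)
#'   before the test stimulus.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(dprime_color = 1.5, dprime_motion = 1.5,
                            criterion = 0.5, lapse_rate = 0,
                            rt_shift_ms = 250, rt_meanlog = log(120),
                            rt_sdlog = 0.3, abort_rate = 0.03) {
  if (dprime_color < 0 || dprime_motion < 0)
    stop("sensitivities must be nonnegative")
  if (rt_shift_ms < 0) stop("rt_shift_ms must be >= 0")
  if (lapse_rate < 0 || lapse_rate >= 1) stop("lapse_rate must be in [0, 1)")
  if (abort_rate < 0 || abort_rate >= 1) stop("abort_rate must be in [0, 1)")
  structure(list(dprime_color = dprime_color, dprime_motion = dprime_motion,
                 criterion = criterion, lapse_rate = lapse_rate,
                 rt_shift_ms = rt_shift_ms, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, abort_rate = abort_rate),
            class = "behavior_params")
}

# evidence draw for one feature; Inf sensitivity is the ideal observer
draw_evidence <- function(matches, dprime) {
  if (!is.finite(dprime)) return(if (matches) Inf else -Inf)
  rnorm(1, mean = if (matches) dprime else 0, sd = 1)
}

#' Simulate the behavioral outcomes of a session
#'
#' Draws trials without replacement from the pool in a random order and
#' simulates the observer described by `params`. Incorrectly answered trials
#' (misses and false alarms) and, optionally, aborted trials are re-queued at
#' a uniformly random later position in the remaining sequence; the original
#' attempt is retained in the output with its outcome.
#'
#' @param pool Trial pool from [build_trial_pool()].
#' @param params A [behavior_params()].
#' @param config The [task_config()] (for delay range and response window).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @param session_id Session identifier stored with every trial.
#' @param reenter_aborted Should aborted trials re-enter the pool like error
#'   trials? The default re-queues them.
#' @param max_attempts Maximum number of times a single pool entry is
#'   presented before it is retired (guards against non-terminating
#'   sessions for very insensitive observers).
#' @return A data.frame of trial records in presentation order with columns
#'   `trial_id`, `session_id`, `pool_id`, `attempt`, `task_type`,
#'   `sample_color`, `sample_motion`, `test_color`, `test_motion`,
#'   `is_target`, `mismatch_type`, `outcome` (hit, miss, false_alarm,
#'   correct_rejection, aborted), `reaction_time_ms` (present iff the outcome
#'   involved a button press), `delay_ms`.
#' @export
simulate_behavior <- function(pool, params, config = task_config(),
                              seed = 1L, session_id = "S1",
                              reenter_aborted = TRUE, max_attempts = 10L) {
  stopifnot(inherits(params, "behavior_params"),
            inherits(config, "task_config"))
  if (nrow(pool) == 0L) stop("trial pool is empty")
  withr::with_seed(as.integer(seed), {
    # queue of pool row indices; re-entries insert at a random later position
    queue <- sample.int(nrow(pool))
    attempts <- rep(1L, length(queue))
    o_row <- integer(0); o_att <- integer(0)
    o_out <- character(0); o_rt <- numeric(0); o_delay <- numeric(0)
    while (length(queue) > 0L) {
      p <- queue[1L]
      att <- attempts[1L]
      queue <- queue[-1L]
      attempts <- attempts[-1L]
      tr <- pool[p, ]
      delay <- runif(1, config$delay_range_ms[1], config$delay_range_ms[2])
      rt <- NA_real_
      if (runif(1) < params$abort_rate) {
        outc <- "aborted"
        reenter <- reenter_aborted
      } else {
        respond <- switch(tr$task_type,
          color = draw_evidence(tr$test_color == tr$sample_color,
                                params$dprime_color) > params$criterion,
          motion = draw_evidence(tr$test_motion == tr$sample_motion,
                                 params$dprime_motion) > params$criterion,
          conjunction = min(
            draw_evidence(tr$test_color == tr$sample_color,
                          params$dprime_color),
            draw_evidence(tr$test_motion == tr$sample_motion,
                          params$dprime_motion)) > params$criterion)
        if (params$lapse_rate > 0 && runif(1) < params$lapse_rate)
          respond <- runif(1) < 0.5
        if (respond) {
          rt <- params$rt_shift_ms + rlnorm(1, params$rt_meanlog,
                                            params$rt_sdlog)
          if (rt > config$response_window_ms) {
            respond <- FALSE          # late press counts as no-response
            rt <- NA_real_
          }
        }
        outc <- if (tr$is_target) {
          if (respond) "hit" else "miss"
        } else {
          if (respond) "false_alarm" else "correct_rejection"
        }
        reenter <- outc %in% c("miss", "false_alarm")
      }
      o_row <- c(o_row, p); o_att <- c(o_att, att)
      o_out <- c(o_out, outc); o_rt <- c(o_rt, rt)
      o_delay <- c(o_delay, delay)
      if (reenter && att < max_attempts) {
        pos <- if (length(queue) == 0L) 1L else sample.int(length(queue) + 1L,
                                                           1L)
        queue <- append(queue, p, after = pos - 1L)
        attempts <- append(attempts, att + 1L, after = pos - 1L)
      }
    }
    records <- pool[o_row, , drop = FALSE]
    records$attempt <- o_att
    records$outcome <- o_out
    records$reaction_time_ms <- o_rt
    records$delay_ms <- o_delay
    records$trial_id <- seq_len(nrow(records))
    records$session_id <- session_id
    rownames(records) <- NULL
    records[, c("trial_id", "session_id", "pool_id", "attempt", "task_type",
                "sample_color", "sample_motion", "test_color", "test_motion",
                "is_target", "mismatch_type", "outcome", "reaction_time_ms",
                "delay_ms")]
  })
}
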