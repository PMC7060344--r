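#' Sensitivity index d-prime from outcome counts
#'
#' Computes `d' = qnorm(hit rate) - qnorm(false-alarm rate)` with the
#' log-linear correction (0.5 added to each cell, 1 to each denominator)
#' applied unconditionally, which keeps d' finite at extreme rates and avoids
#' a discontinuity between corrected and uncorrected counts.
#'
#' @param n_hit,n_miss,n_fa,n_cr Outcome counts. Both the target side
#'   (`n_hit + n_miss`) and the non-target side (`n_fa + n_cr`) must contain
#'   at least one trial.
#' @return The sensitivity index (numeric scalar).
#' @export
dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  counts <- c(n_hit, n_miss, n_fa, n_cr)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (n_hit + n_miss < 1 || n_fa + n_cr < 1)
    stop("d-prime undefined: need at least one target and one non-target trial")
  hr <- (n_hit + 0.5) / (n_hit + n_miss + 1)
  far <- (n_fa + 0.5) / (n_fa + n_cr + 1)
  qnorm(hr) - qnorm(far)
}

count_outcomes <- function(records) {
  c(n_hit = sum(records$outcome == "hit"),
    n_miss = sum(records$outcome == "miss"),
    n_fa = sum(records$outcome == "false_alarm"),
    n_cr = sum(records$outcome == "correct_rejection"))
}

#' Per-session d-prime by mismatch contrast
#'
#' For conjunction trials, targets (full matches) are contrasted separately
#' with each of the three mismatch types: color-only mismatches (the test
#' differs from the sample only in color, so discrimination rests on the
#' color feature), motion-only mismatches, and complete mismatches. The
#' single-feature tasks contribute one d' each. Contrast names:
#' `conjunction_color`, `conjunction_motion`, `conjunction_complete`,
#' `color_task`, `motion_task`.
#'
#' @param records Trial records (possibly several sessions).
#' @return A data.frame with columns `session_id`, `contrast`, `dprime`,
#'   `n_target`, `n_nontarget`. A session lacking trials for a contrast gets
#'   `NA` and a message.
#' @export
dprime_by_contrast <- function(records) {
  out <- list()
  for (sid in unique(records$session_id)) {
    rs <- records[records$session_id == sid & records$outcome != "aborted", ]
    conj <- rs[rs$task_type == "conjunction", ]
    tgt <- count_outcomes(conj[conj$is_target, ])
    for (mm in c("color", "motion", "complete")) {
      non <- count_outcomes(conj[conj$mismatch_type == mm, ])
      out[[length(out) + 1L]] <- contrast_row(
        sid, paste0("conjunction_", mm), tgt, non)
    }
    for (tt in c("color", "motion")) {
      ts <- rs[rs$task_type == tt, ]
      out[[length(out) + 1L]] <- contrast_row(
        sid, paste0(tt, "_task"), count_outcomes(ts[ts$is_target, ]),
        count_outcomes(ts[!ts$is_target, ]))
    }
  }
  do.call(rbind, out)
}

contrast_row <- function(sid, contrast, tgt, non) {
  n_t <- tgt[["n_hit"]] + tgt[["n_miss"]]
  n_n <- non[["n_fa"]] + non[["n_cr"]]
  dp <- if (n_t >= 1 && n_n >= 1) {
    dprime(tgt[["n_hit"]], tgt[["n_miss"]], non[["n_fa"]], non[["n_cr"]])
  } else {
    message("session ", sid, ": no trials for contrast '", contrast,
            "', d-prime set to NA")
    NA_real_
  }
  data.frame(session_id = sid, contrast = contrast, dprime = dp,
             n_target = n_t, n_nontarget = n_n, stringsAsFactors = FALSE)
}

#' Paired across-session tests between d-prime contrasts
#'
#' Paired-sample t-tests of session-wise d' values between contrast pairs,
#' evaluated at a Bonferroni-corrected alpha. The default comparisons test
#' whether single-feature mismatches are harder than complete mismatches,
#' whether one feature dominates the other (feature bias), and whether
#' single-task performance differs from the matched conjunction contrast.
#'
#' @param dp A data.frame from [dprime_by_contrast()].
#' @param comparisons List of length-2 character vectors of contrast names.
#' @param alpha Corrected significance level (default 0.005).
#' @return A data.frame with one row per comparison: `contrast_a`,
#'   `contrast_b`, `mean_diff`, `t`, `df`, `p`, `n_sessions`, `significant`.
#'   With a single session the tests are skipped with a warning.
#' @export
contrast_tests <- function(dp, comparisons = list(
                             c("conjunction_complete", "conjunction_color"),
                             c("conjunction_complete", "conjunction_motion"),
                             c("conjunction_motion", "conjunction_color"),
                             c("conjunction_color", "color_task"),
                             c("conjunction_motion", "motion_task")),
                           alpha = 0.005) {
  wide <- split(dp, dp$contrast)
  out <- list()
  for (cmp in comparisons) {
    a <- wide[[cmp[1]]]; b <- wide[[cmp[2]]]
    if (is.null(a) || is.null(b)) next
    m <- merge(a[, c("session_id", "dprime")], b[, c("session_id", "dprime")],
               by = "session_id", suffixes = c("_a", "_b"))
    m <- m[complete.cases(m), ]
    if (nrow(m) < 2L) {
      warning("comparison ", cmp[1], " vs ", cmp[2],
              ": fewer than 2 sessions, paired test skipped")
      next
    }
    tt <- t.test(m$dprime_a, m$dprime_b, paired = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      contrast_a = cmp[1], contrast_b = cmp[2],
      mean_diff = unname(tt$estimate), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value, n_sessions = nrow(m),
      significant = tt$p.value < alpha, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Compare two reaction time groups on the speed scale
#'
#' Normalizes reaction times to speed (reciprocal latency, 1/s) and runs a
#' two-sample t-test, plus two robustness checks: the same t-test on raw
#' latencies and a rank-based Wilcoxon test.
#'
#' @param rts_a,rts_b Reaction times in ms (each group >= 2 values). The
#'   caller is expected to have applied the 300 ms exclusion; values below
#'   300 ms trigger a warning.
#' @return A data.frame with rows `speed_t`, `raw_t`, `wilcoxon`: columns
#'   `method`, `statistic`, `p`, `n_a`, `n_b`.
#' @export
rt_compare <- function(rts_a, rts_b) {
  if (length(rts_a) < 2L || length(rts_b) < 2L)
    stop("each group needs at least 2 reaction times")
  if (any(c(rts_a, rts_b) < 300))
    warning("reaction times below 300 ms present; the exclusion rule is ",
            "expected to be applied upstream")
  sp_a <- 1000 / rts_a
  sp_b <- 1000 / rts_b
  tt <- function(x, y) {
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
      return(list(statistic = 0, p.value = 1))  # identical groups
    t.test(x, y, var.equal = TRUE)
  }
  t_sp <- tt(sp_a, sp_b)
  t_raw <- tt(rts_a, rts_b)
  wx <- suppressWarnings(wilcox.test(rts_a, rts_b))
  data.frame(
    method = c("speed_t", "raw_t", "wilcoxon"),
    statistic = c(unname(t_sp$statistic), unname(t_raw$statistic),
                  unname(wx$statistic)),
    p = c(t_sp$p.value, t_raw$p.value, wx$p.value),
    mean_a = c(mean(sp_a), mean(rts_a), stats::median(rts_a)),
    mean_b = c(mean(sp_b), mean(rts_b), stats::median(rts_b)),
    n_a = length(rts_a), n_b = length(rts_b), stringsAsFactors = FALSE)
}
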