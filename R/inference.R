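#' Permutation null ensemble for a decoding analysis
#'
#' Re-executes the full decoding run `n_perm` times. Every run independently
#' re-draws the balancing exclusions, the cross-validation splits and the
#' pseudo-trial groupings, and then uniformly shuffles the labels of the
#' averaged training pseudo-trials (test labels untouched) before the
#' classifiers are fit. The fold-averaged accuracy traces of these runs form
#' the empirical chance distribution.
#'
#' @inheritParams decode_timecourse
#' @param n_perm Number of permutation runs (>= 2; 500 for full-scale
#'   analyses).
#' @return An object of class `null_ensemble`: `accuracies` (n_perm x bins,
#'   fold-averaged per run), `time_ms`, `n_perm`, `n_classes`, `chance`,
#'   `seed`.
#' @export
permutation_null <- function(dataset, spec = decoder_spec(), n_perm = 500,
                             seed = 1L, balance = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "decoder_spec"))
  if (n_perm < 2) stop("n_perm must be at least 2")
  run_seeds <- derive_seeds(seed, 3L * n_perm)
  B <- length(dataset$epochs$time_ms)
  acc <- matrix(NA_real_, n_perm, B)
  n_classes <- NULL
  for (r in seq_len(n_perm)) {
    s <- run_seeds[(3L * (r - 1L) + 1L):(3L * r)]
    idx <- if (balance)
      balance_trials(dataset$labels, dataset$covariates, seed = s[1])
    else seq_along(dataset$labels)
    run <- decode_run(dataset$epochs, dataset$labels, spec, seed = s[2],
                      shuffle = TRUE, balance_idx = idx, split_seed = s[3])
    acc[r, ] <- colMeans(run$acc)
    n_classes <- run$n_classes
  }
  structure(list(accuracies = acc, time_ms = dataset$epochs$time_ms,
                 n_perm = n_perm, n_classes = n_classes,
                 chance = 1 / n_classes, seed = seed),
            class = "null_ensemble")
}

check_axes <- function(time_a, time_b) {
  if (length(time_a) != length(time_b) ||
      any(abs(time_a - time_b) > 1e-9))
    stop("time axes do not match")
}

#' Per-bin significance of decoding against the permutation null
#'
#' Tests, per time bin, whether the observed mean accuracy exceeds chance
#' with a one-sided z-test against the permutation null's mean and standard
#' deviation.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param null A `null_ensemble` on the same time axis.
#' @param alpha Per-bin significance threshold (default 1e-4).
#' @return An object of class `significance_trace`: data.frame with
#'   `time_ms`, `z`, `p` (one-sided upper), `significant`; attribute `alpha`.
#' @export
significance_trace <- function(timecourse, null, alpha = 1e-4) {
  stopifnot(inherits(timecourse, "decoding_timecourse"),
            inherits(null, "null_ensemble"))
  check_axes(timecourse$time_ms, null$time_ms)
  mu <- colMeans(null$accuracies)
  sdv <- apply(null$accuracies, 2, sd)
  if (any(sdv == 0)) stop("degenerate null: zero standard deviation at ",
                          sum(sdv == 0), " bin(s)")
  z <- (timecourse$mean_accuracy - mu) / sdv
  out <- data.frame(time_ms = timecourse$time_ms, z = z,
                    p = pnorm(z, lower.tail = FALSE),
                    significant = pnorm(z, lower.tail = FALSE) < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("significance_trace", "data.frame")
  out
}

# onset of the earliest fully-significant window over a logical vector
scan_onset <- function(time_ms, significant, window_ms) {
  dt <- unique(round(diff(time_ms), 9))
  if (length(dt) != 1L) stop("time grid must be uniform")
  n_win <- as.integer(round(window_ms / dt)) + 1L  # inclusive of both ends
  if (n_win < 2L) stop("window_ms must span at least 2 bins")
  B <- length(significant)
  if (n_win > B) return(NA_real_)
  run <- rle(significant)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cand <- which(run$values & run$lengths >= n_win)
  if (!length(cand)) return(NA_real_)
  i <- starts[cand[1]]
  (time_ms[i] + time_ms[i + n_win - 1L]) / 2
}

#' Decoding onset latency
#'
#' The onset is the center of the earliest window spanning `window_ms`
#' (inclusive of both end bins, i.e. 11 bins at 4 ms spacing for 40 ms) in
#' which every time bin is significant; absent when no such window exists.
#'
#' @param trace A `significance_trace`.
#' @param window_ms Required duration of sustained significance.
#' @return An object of class `onset_estimate`: list with `onset_ms`
#'   (`NA` when absent), `window_ms`, `n_bins`.
#' @export
detect_onset <- function(trace, window_ms = 40) {
  stopifnot(inherits(trace, "significance_trace"))
  onset <- scan_onset(trace$time_ms, trace$significant, window_ms)
  dt <- round(diff(trace$time_ms)[1], 9)
  structure(list(onset_ms = onset, window_ms = window_ms,
                 n_bins = as.integer(round(window_ms / dt)) + 1L),
            class = "onset_estimate")
}

#' Per-fold onset latencies
#'
#' Computes the significance trace and onset separately for every testing
#' fold's accuracy trace, against the same (fold-averaged) null. Folds
#' without a qualifying sustained-significance window yield `NA`; the number
#' of such exclusions is reported as an attribute.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param null A `null_ensemble` on the same time axis.
#' @param alpha Per-bin significance threshold.
#' @param window_ms Required duration of sustained significance.
#' @return Numeric vector of per-fold onsets (ms; `NA` = absent), with
#'   attribute `n_absent`.
#' @export
fold_onsets <- function(timecourse, null, alpha = 1e-4, window_ms = 40) {
  stopifnot(inherits(timecourse, "decoding_timecourse"),
            inherits(null, "null_ensemble"))
  check_axes(timecourse$time_ms, null$time_ms)
  mu <- colMeans(null$accuracies)
  sdv <- apply(null$accuracies, 2, sd)
  if (any(sdv == 0)) stop("degenerate null")
  onsets <- apply(timecourse$accuracy, 1, function(a) {
    p <- pnorm((a - mu) / sdv, lower.tail = FALSE)
    scan_onset(timecourse$time_ms, p < alpha, window_ms)
  })
  attr(onsets, "n_absent") <- sum(is.na(onsets))
  onsets
}

#' Compare fold-onset distributions of two conditions
#'
#' @param onsets_a,onsets_b Per-fold onsets from [fold_onsets()]; `NA`
#'   entries (folds without a qualifying window) are excluded and reported.
#' @return List with `t`, `df`, `p`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `skipped` (TRUE when fewer than 2 folds with onsets on either side).
#' @export
compare_fold_onsets <- function(onsets_a, onsets_b) {
  a <- onsets_a[!is.na(onsets_a)]
  b <- onsets_b[!is.na(onsets_b)]
  if (length(a) < 2L || length(b) < 2L) {
    message("fold-onset comparison skipped: fewer than 2 folds with onsets (",
            length(a), " vs ", length(b), ")")
    return(list(skipped = TRUE, n_a = length(a), n_b = length(b)))
  }
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate but well-defined: identical constants tie, distinct ones
    # separate perfectly
    eq <- mean(a) == mean(b)
    return(list(skipped = FALSE, t = if (eq) 0 else Inf * sign(mean(a) -
                                                                 mean(b)),
                df = length(a) + length(b) - 2, p = if (eq) 1 else 0,
                n_a = length(a), n_b = length(b),
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(skipped = FALSE, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' Between-condition decoding contrast
#'
#' Per time bin, compares the two conditions' fold accuracies with two-sample
#' t-tests at a Bonferroni-corrected alpha, and reports all maximal runs of
#' significant bins spanning at least `window_ms` together with their onsets
#' (center of the first fully-significant window within each run). When
#' permutation nulls are supplied, per-fold onset distributions are also
#' compared.
#'
#' @param tc_a,tc_b `decoding_timecourse` objects on the same time axis with
#'   equal fold counts.
#' @param alpha Bonferroni-corrected per-bin alpha (default 0.05/3).
#' @param window_ms Minimum duration of a reported difference epoch.
#' @param null_a,null_b Optional `null_ensemble`s for the fold-onset
#'   comparison.
#' @param onset_alpha Per-bin alpha used for the fold-onset traces.
#' @return An object of class `condition_contrast`: `per_bin` data.frame
#'   (`time_ms`, `t`, `p`, `significant`), `epochs` data.frame (`start_ms`,
#'   `end_ms`, `onset_ms`; zero rows when no epoch qualifies), and
#'   `fold_onset_test` (or `NULL`).
#' @export
compare_conditions <- function(tc_a, tc_b, alpha = 0.05 / 3, window_ms = 40,
                               null_a = NULL, null_b = NULL,
                               onset_alpha = 1e-4) {
  stopifnot(inherits(tc_a, "decoding_timecourse"),
            inherits(tc_b, "decoding_timecourse"))
  check_axes(tc_a$time_ms, tc_b$time_ms)
  if (nrow(tc_a$accuracy) != nrow(tc_b$accuracy))
    stop("fold counts differ between conditions")
  B <- length(tc_a$time_ms)
  tv <- pv <- numeric(B)
  for (b in seq_len(B)) {
    x <- tc_a$accuracy[, b]; y <- tc_b$accuracy[, b]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      tv[b] <- 0; pv[b] <- 1
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
      tv[b] <- unname(tt$statistic); pv[b] <- tt$p.value
    }
  }
  sig <- pv < alpha
  dt <- round(diff(tc_a$time_ms)[1], 9)
  n_win <- as.integer(round(window_ms / dt)) + 1L
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  keep <- which(run$values & run$lengths >= n_win)
  epochs <- data.frame(start_ms = tc_a$time_ms[starts[keep]],
                       end_ms = tc_a$time_ms[ends[keep]],
                       onset_ms = (tc_a$time_ms[starts[keep]] +
                                     tc_a$time_ms[starts[keep] + n_win - 1L]) / 2)
  fot <- NULL
  if (!is.null(null_a) && !is.null(null_b))
    fot <- compare_fold_onsets(
      fold_onsets(tc_a, null_a, onset_alpha, window_ms),
      fold_onsets(tc_b, null_b, onset_alpha, window_ms))
  structure(list(per_bin = data.frame(time_ms = tc_a$time_ms, t = tv, p = pv,
                                      significant = sig),
                 epochs = epochs, fold_onset_test = fot,
                 alpha = alpha, window_ms = window_ms),
            class = "condition_contrast")
}
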