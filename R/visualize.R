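#' Moving-average decoding trace with confidence band
#'
#' Smooths each fold's accuracy trace with a centered moving average spanning
#' `window_ms` (7 bins at 4 ms spacing for the default 28 ms) and returns the
#' smoothed fold mean with its 95% confidence interval across folds. Display
#' only; never used for statistics. Edge bins use the renormalized partial
#' window.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param window_ms Smoothing window duration.
#' @param level Confidence level of the across-fold interval.
#' @return Data.frame with `time_ms`, `mean`, `lo`, `hi`.
#' @export
moving_average_ci <- function(timecourse, window_ms = 28, level = 0.95) {
  stopifnot(inherits(timecourse, "decoding_timecourse"))
  t <- timecourse$time_ms
  dt <- round(diff(t)[1], 9)
  k <- as.integer(round(window_ms / dt))
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  B <- length(t)
  smooth_one <- function(x) {
    vapply(seq_len(B), function(i) {
      lo <- max(1L, i - half); hi <- min(B, i + half)
      mean(x[lo:hi])
    }, numeric(1))
  }
  sm <- t(apply(timecourse$accuracy, 1, smooth_one))
  m <- colMeans(sm)
  se <- apply(sm, 2, sd) / sqrt(nrow(sm))
  q <- stats::qt(1 - (1 - level) / 2, df = nrow(sm) - 1)
  data.frame(time_ms = t, mean = m, lo = m - q * se, hi = m + q * se)
}

#' Chance band of the shuffle distribution
#'
#' Per-bin 99.9% band of the permutation null, for plotting against the
#' decoding trace. The default band is the normal approximation
#' `mean +/- qnorm(0.9995) * sd` of the shuffle runs, consistent with the
#' z-test used for inference; `method = "percentile"` gives the empirical
#' 0.05th-99.95th percentile band instead.
#'
#' @param null A `null_ensemble`.
#' @param level Band coverage (default 0.999).
#' @param method `"normal"` or `"percentile"`.
#' @return Data.frame with `time_ms`, `lo`, `hi`.
#' @export
null_band <- function(null, level = 0.999,
                      method = c("normal", "percentile")) {
  stopifnot(inherits(null, "null_ensemble"))
  method <- match.arg(method)
  a <- (1 - level) / 2
  if (method == "normal") {
    mu <- colMeans(null$accuracies)
    sdv <- apply(null$accuracies, 2, sd)
    q <- qnorm(1 - a)
    data.frame(time_ms = null$time_ms, lo = mu - q * sdv, hi = mu + q * sdv)
  } else {
    qs <- apply(null$accuracies, 2, quantile, probs = c(a, 1 - a))
    data.frame(time_ms = null$time_ms, lo = qs[1, ], hi = qs[2, ])
  }
}

#' Cumulative reaction-time distribution of a trial group
#'
#' Cumulative fraction of responded trials as a function of time since test
#' onset, normalized so that 100% equals all button presses in the group;
#' the 300 ms response floor is recorded as an attribute.
#'
#' @param records Trial records (already filtered to the group of interest).
#' @param floor_ms Response floor to mark (ms).
#' @return Data.frame with `time_ms` and `cum_fraction` (nondecreasing,
#'   reaching 1 at the slowest press), attribute `floor_ms`.
#' @export
cumulative_rt_overlay <- function(records, floor_ms = 300) {
  rts <- records$reaction_time_ms[!is.na(records$reaction_time_ms)]
  if (!length(rts)) stop("no responded trials in the group")
  rts <- sort(rts)
  out <- data.frame(time_ms = rts,
                    cum_fraction = seq_along(rts) / length(rts))
  attr(out, "floor_ms") <- floor_ms
  out
}

#' Plot a decoding timecourse against its chance band
#'
#' Assembles the smoothed decoding trace with its 95% CI, the 99.9% shuffle
#' band, significance markers, and (optionally) the cumulative reaction time
#' distribution, in the style of time-resolved decoding figures. Requires
#' ggplot2.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param null A `null_ensemble`.
#' @param trace Optional `significance_trace` for significance dots.
#' @param rt_records Optional trial records for the RT overlay.
#' @return A ggplot object.
#' @export
plot_decoding <- function(timecourse, null, trace = NULL,
                          rt_records = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_decoding requires ggplot2")
  ma <- moving_average_ci(timecourse)
  nb <- null_band(null)
  g <- ggplot2::ggplot(ma, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(data = nb,
                         ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::geom_hline(yintercept = timecourse$chance, linetype = 3) +
    ggplot2::labs(x = "time from event (ms)", y = "decoding accuracy")
  if (!is.null(trace) && any(trace$significant)) {
    sig <- data.frame(time_ms = trace$time_ms[trace$significant],
                      y = min(nb$lo) - 0.02)
    g <- g + ggplot2::geom_point(data = sig,
                                 ggplot2::aes(y = .data$y), size = 0.6,
                                 color = "steelblue")
  }
  if (!is.null(rt_records)) {
    cdf <- cumulative_rt_overlay(rt_records)
    rng <- range(c(nb$lo, ma$hi))
    cdf$scaled <- rng[1] + cdf$cum_fraction * diff(rng)
    g <- g + ggplot2::geom_step(data = cdf,
                                ggplot2::aes(y = .data$scaled),
                                color = "darkorange") +
      ggplot2::geom_vline(xintercept = attr(cdf, "floor_ms"),
                          linetype = 2, color = "darkorange")
  }
  g
}
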