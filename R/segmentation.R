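#' Remove questionnaire-response windows from a sensor stream
#'
#' Drops every sample whose timestamp falls inside any registered response
#' window `[start, end)` of the schedule — the proband was busy answering the
#' in-task questionnaire, not learning. Order of the remaining samples is
#' preserved. Works on a single stream (`al_timeseries`) or on a whole
#' band-power set (`al_bandpower`, all 25 streams share timestamps so the
#' same rows are dropped from each).
#'
#' @param x An `al_timeseries` or `al_bandpower`.
#' @param schedule An `al_schedule` with registered responses.
#' @return Object of the same class with masked samples removed.
#' @export
mask_response_windows <- function(x, schedule) {
  stopifnot(inherits(schedule, "al_schedule"))
  UseMethod("mask_response_windows")
}

masked_keep <- function(t, schedule) {
  win <- response_windows(schedule)
  keep <- rep(TRUE, length(t))
  for (i in seq_len(nrow(win))) {
    keep <- keep & !(t >= win[i, 1L] & t < win[i, 2L])
  }
  keep
}

#' @export
mask_response_windows.al_timeseries <- function(x, schedule) {
  keep <- masked_keep(x$t, schedule)
  out <- timeseries(x$t[keep], x$v[keep], x$nominal_rate)
  attr(out, "units") <- attr(x, "units")
  out
}

#' @export
mask_response_windows.al_bandpower <- function(x, schedule) {
  keep <- masked_keep(x$t, schedule)
  bandpower_set(x$t[keep], x$power[keep, , drop = FALSE], x$nominal_rate)
}

new_segment <- function(index, window, data, nominal_n) {
  n <- if (inherits(data, "al_bandpower")) length(data$t) else length(data$t)
  coverage <- if (nominal_n > 0) min(1, n / nominal_n) else 0
  structure(list(index = index, window = window, data = data,
                 coverage = coverage, flagged = coverage < 0.5),
            class = "al_segment")
}

#' @export
print.al_segment <- function(x, ...) {
  cat(sprintf("<al_segment> #%d [%g, %g) coverage %.3f%s\n", x$index,
              x$window[1], x$window[2], x$coverage,
              if (x$flagged) " (flagged: low coverage)" else ""))
  invisible(x)
}

#' Slice a stream into the 13 pre-sample segments
#'
#' Segment k covers the half-open interval `[alarm_k - interval, alarm_k)` —
#' the sensor data preceding experience sample k. Segments are anchored to the
#' nominal alarm times, are non-overlapping, and jointly cover
#' `(0, last alarm)`. The input should already be masked with
#' [mask_response_windows()] (masking and slicing commute, so the order is
#' immaterial). Each segment records its coverage, the retained share of the
#' nominal `interval * nominal_rate` samples; coverage below 0.5 is flagged.
#'
#' @param x An `al_timeseries` or `al_bandpower` (masked).
#' @param schedule An `al_schedule`.
#' @return List of `al_segment`, one per alarm, `$index` = 1..K.
#' @export
segment_preceding <- function(x, schedule) {
  stopifnot(inherits(schedule, "al_schedule"))
  rate <- x$nominal_rate
  lapply(seq_along(schedule$alarms), function(k) {
    a <- schedule$alarms[k]
    win <- c(a - schedule$interval, a)
    data <- slice_window(x, win[1], win[2])
    new_segment(k, win, data, nominal_n = schedule$interval * rate)
  })
}

slice_window <- function(x, start, end) {
  if (inherits(x, "al_bandpower")) {
    keep <- x$t >= start & x$t < end
    bandpower_set(x$t[keep], x$power[keep, , drop = FALSE], x$nominal_rate)
  } else {
    ts_window(x, start, end)
  }
}

#' Whole-session segment (index 0)
#'
#' The full session stream with the questionnaire-response windows masked
#' out — the input for outcome-level features. For the standard design
#' (13 answers averaging ~16 s in a 3600 s session) coverage is about 0.94.
#'
#' @param x An `al_timeseries` or `al_bandpower` (unmasked; masking is applied
#'   here).
#' @param schedule An `al_schedule`.
#' @return An `al_segment` with `$index = 0`.
#' @export
whole_session <- function(x, schedule) {
  stopifnot(inherits(schedule, "al_schedule"))
  masked <- mask_response_windows(x, schedule)
  new_segment(0L, c(0, schedule$session_length), masked,
              nominal_n = schedule$session_length * x$nominal_rate)
}
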