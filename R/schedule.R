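#' Build an experience-sampling schedule
#'
#' Alarms fire every `interval` seconds through the session: alarm k at
#' `interval * k` for `k = 1 .. floor(session_length / interval)`. A 3600 s
#' session with 270 s intervals therefore yields 13 alarms. Each alarm opens a
#' response window starting at the alarm; an answer counts as valid only if it
#' is completed within `response_limit` seconds. Windows are initialised
#' empty/invalid until responses are registered with
#' [register_responses()].
#'
#' @param session_length Session length in seconds (>= `interval`).
#' @param interval Alarm interval in seconds (> 0).
#' @param response_limit Response time limit in seconds (default 60).
#' @return An object of class `al_schedule`: list with `session_length`,
#'   `interval`, `response_limit`, `alarms`, `resp_start`, `resp_end`
#'   (NA until registered) and logical `valid`.
#' @examples
#' sch <- build_schedule(3600, 270, 60)
#' length(sch$alarms)  # 13
#' @export
build_schedule <- function(session_length, interval, response_limit = 60) {
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("build_schedule: `interval` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(session_length) || length(session_length) != 1L ||
      session_length < interval) {
    stop("build_schedule: `session_length` must be >= `interval`", call. = FALSE)
  }
  if (response_limit <= 0) {
    stop("build_schedule: `response_limit` must be positive", call. = FALSE)
  }
  session_length <- as.numeric(session_length)
  interval <- as.numeric(interval)
  k <- floor(session_length / interval)
  alarms <- interval * seq_len(k)
  structure(list(
    session_length = as.numeric(session_length),
    interval       = as.numeric(interval),
    response_limit = as.numeric(response_limit),
    alarms         = alarms,
    resp_start     = rep(NA_real_, k),
    resp_end       = rep(NA_real_, k),
    valid          = rep(FALSE, k)
  ), class = "al_schedule")
}

#' Register questionnaire response durations on a schedule
#'
#' Response k occupies the half-open window `[alarm_k, alarm_k + duration_k)`.
#' A missing duration (`NA`) means no answer was given; a duration above the
#' response limit means the answer came too late. Both mark the alarm invalid;
#' late answers still mask sensor data up to the limit (the proband was busy
#' with the questionnaire during that time).
#'
#' @param schedule An `al_schedule` from [build_schedule()].
#' @param durations Numeric vector, one response duration (s) per alarm; `NA`
#'   for unanswered alarms.
#' @return The schedule with `resp_start`, `resp_end` and `valid` filled in.
#' @export
register_responses <- function(schedule, durations) {
  stopifnot(inherits(schedule, "al_schedule"))
  k <- length(schedule$alarms)
  if (length(durations) != k) {
    stop("register_responses: need one duration per alarm", call. = FALSE)
  }
  durations <- as.numeric(durations)
  if (any(durations <= 0, na.rm = TRUE)) {
    stop("register_responses: durations must be positive", call. = FALSE)
  }
  answered <- !is.na(durations)
  schedule$valid <- answered & durations <= schedule$response_limit
  schedule$resp_start <- ifelse(answered, schedule$alarms, NA_real_)
  schedule$resp_end <- ifelse(
    answered,
    schedule$alarms + pmin(durations, schedule$response_limit),
    NA_real_
  )
  schedule
}

#' Response windows of a schedule
#' @param schedule An `al_schedule`.
#' @return Two-column matrix `(start, end)` of the registered response
#'   windows, one row per answered alarm (invalid late answers included:
#'   their sensor data are still occluded).
#' @export
response_windows <- function(schedule) {
  ok <- !is.na(schedule$resp_start)
  cbind(start = schedule$resp_start[ok], end = schedule$resp_end[ok])
}

#' @export
print.al_schedule <- function(x, ...) {
  cat(sprintf("<al_schedule> %g s session, alarms every %g s: %d alarms, %d valid responses\n",
              x$session_length, x$interval, length(x$alarms), sum(x$valid)))
  invisible(x)
}
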