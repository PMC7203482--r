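#' Sensor time series
#'
#' The atom every feature is computed on: a single timestamped sensor channel
#' with a nominal sampling rate. Timestamps are seconds from session start and
#' must be strictly increasing; intervals are half-open `[start, end)`
#' throughout the package.
#'
#' @param t Numeric vector of timestamps (seconds from session start,
#'   non-negative, strictly increasing).
#' @param v Numeric vector of sensor values, same length as `t`.
#' @param nominal_rate Nominal sampling rate in Hz (> 0).
#' @return An object of class `al_timeseries`: a list with elements `t`, `v`
#'   and `nominal_rate`.
#' @examples
#' ts <- timeseries(0:9, rnorm(10), nominal_rate = 1)
#' ts_duration(ts)
#' @export
timeseries <- function(t, v, nominal_rate) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("timeseries: `t` and `v` must have equal length", call. = FALSE)
  }
  if (length(t) && (anyNA(t) || any(t < 0))) {
    stop("timeseries: timestamps must be non-negative and non-missing", call. = FALSE)
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timeseries: timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0) {
    stop("timeseries: `nominal_rate` must be a single positive number", call. = FALSE)
  }
  structure(list(t = t, v = v, nominal_rate = as.numeric(nominal_rate)),
            class = "al_timeseries")
}

#' @export
print.al_timeseries <- function(x, ...) {
  cat(sprintf("<al_timeseries> %d samples @ %g Hz nominal, t in [%s, %s]\n",
              length(x$t), x$nominal_rate,
              if (length(x$t)) format(min(x$t)) else "-",
              if (length(x$t)) format(max(x$t)) else "-"))
  invisible(x)
}

#' @export
length.al_timeseries <- function(x) length(x$t)

#' Duration spanned by a time series
#' @param ts An `al_timeseries`.
#' @return `max(t) - min(t)` in seconds, or 0 for streams with < 2 samples.
#' @export
ts_duration <- function(ts) {
  if (length(ts$t) < 2L) return(0)
  max(ts$t) - min(ts$t)
}

#' Restrict a time series to a half-open time window
#' @param ts An `al_timeseries`.
#' @param start,end Window bounds in seconds; samples with
#'   `start <= t < end` are kept.
#' @return An `al_timeseries` (possibly empty).
#' @export
ts_window <- function(ts, start, end) {
  keep <- ts$t >= start & ts$t < end
  timeseries(ts$t[keep], ts$v[keep], ts$nominal_rate)
}

# Electrode and band vocabularies of the 5-channel consumer headset.
# Band edges in Hz, half-open [low, high).
#' @export
EEG_SITES <- c("AF3", "AF4", "T7", "T8", "Pz")

#' @export
EEG_BANDS <- c("theta", "alpha", "beta_low", "beta_high", "gamma")

#' Canonical EEG band edges
#'
#' Half-open frequency intervals `[low, high)` in Hz for the five bands the
#' headset reports: theta 4-8, alpha 8-12, lower beta 12-16, upper beta 16-25,
#' gamma 25-45.
#' @return Named list of length-2 numeric vectors.
#' @export
eeg_band_edges <- function() {
  list(theta     = c(4, 8),
       alpha     = c(8, 12),
       beta_low  = c(12, 16),
       beta_high = c(16, 25),
       gamma     = c(25, 45))
}

#' Band-power set
#'
#' The aligned collection of 25 EEG band-power streams (5 electrodes x 5
#' bands) sharing one timestamp vector. Stored as a time-by-stream matrix so
#' masking and segmentation act on all streams at once.
#'
#' @param t Shared timestamp vector (strictly increasing, non-negative).
#' @param power Numeric matrix, `length(t)` rows, 25 columns named
#'   `"<SITE>_<band>"` (e.g. `"T7_gamma"`); all values must be >= 0.
#' @param nominal_rate Nominal rate in Hz (default 8, the headset's output
#'   rate).
#' @return An object of class `al_bandpower`.
#' @export
bandpower_set <- function(t, power, nominal_rate = 8) {
  t <- as.numeric(t)
  if (!is.matrix(power)) power <- as.matrix(power)
  expected <- bp_stream_names()
  if (is.null(colnames(power)) || !setequal(colnames(power), expected)) {
    stop("bandpower_set: `power` must have the 25 <SITE>_<band> columns", call. = FALSE)
  }
  power <- power[, expected, drop = FALSE]
  if (nrow(power) != length(t)) {
    stop("bandpower_set: `power` rows must match length(t)", call. = FALSE)
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("bandpower_set: timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(power) && any(power < 0)) {
    stop("bandpower_set: band-power values must be non-negative", call. = FALSE)
  }
  structure(list(t = t, power = power, nominal_rate = as.numeric(nominal_rate)),
            class = "al_bandpower")
}

#' The 25 canonical band-power stream names
#' @return Character vector `"<SITE>_<band>"`, sites varying slowest.
#' @export
bp_stream_names <- function() {
  as.vector(t(outer(EEG_SITES, EEG_BANDS, paste, sep = "_")))
}

#' Extract one band-power stream as a time series
#' @param bp An `al_bandpower`.
#' @param site Electrode, one of `EEG_SITES`.
#' @param band Band, one of `EEG_BANDS`.
#' @return An `al_timeseries`.
#' @export
bp_stream <- function(bp, site, band) {
  site <- match.arg(site, EEG_SITES)
  band <- match.arg(band, EEG_BANDS)
  timeseries(bp$t, bp$power[, paste(site, band, sep = "_")], bp$nominal_rate)
}

#' @export
print.al_bandpower <- function(x, ...) {
  cat(sprintf("<al_bandpower> 25 streams x %d samples @ %g Hz nominal\n",
              length(x$t), x$nominal_rate))
  invisible(x)
}

#' Electrodermal activity stream
#'
#' Galvanic skin resistance (kOhm) sampled by the wristband at a nominal
#' 5 Hz. Resistance must be strictly positive.
#'
#' @param t,v Timestamps (s) and resistance values (kOhm).
#' @param nominal_rate Nominal rate in Hz (default 5).
#' @return An `al_timeseries` with attribute `units = "kOhm"`.
#' @export
eda_stream <- function(t, v, nominal_rate = 5) {
  if (length(v) && any(v <= 0)) {
    stop("eda_stream: skin resistance must be strictly positive", call. = FALSE)
  }
  ts <- timeseries(t, v, nominal_rate)
  attr(ts, "units") <- "kOhm"
  ts
}
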