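FEATURE_STATS <- c("mean", "median", "std", "max", "min", "maxmin", "tendency")

# The 7 summary statistics on (t, v) within the nominal window [w0, w1).
# tendency = median(first 30 s) - median(last 30 s) of the window's time span;
# std uses the sample (n-1) denominator; maxmin = max - min.
stream_stats <- function(t, v, window) {
  if (!length(v)) {
    return(stats::setNames(rep(NA_real_, 7L), FEATURE_STATS))
  }
  first30 <- v[t < window[1] + 30]
  last30 <- v[t >= window[2] - 30]
  tendency <- if (length(first30) && length(last30)) {
    stats::median(first30) - stats::median(last30)
  } else NA_real_
  mx <- max(v); mn <- min(v)
  c(mean = mean(v), median = stats::median(v),
    std = if (length(v) > 1L) stats::sd(v) else NA_real_,
    max = mx, min = mn, maxmin = mx - mn, tendency = tendency)
}

#' The seven summary features of a segment
#'
#' mean, median, standard deviation (sample, n-1), maximum, minimum, range
#' (`maxmin = max - min`) and `tendency`, the difference between the medians
#' of the first 30 s and the last 30 s of the segment's nominal time span.
#' An empty segment yields all-`NA` features; `tendency` is `NA` whenever
#' either 30 s end-window holds no samples.
#'
#' @param seg An `al_segment` whose `$data` is an `al_timeseries`.
#' @return Named numeric vector of length 7.
#' @examples
#' sch <- build_schedule(270, 270)
#' seg <- segment_preceding(timeseries(0:269, 0:269, 1), sch)[[1]]
#' summary_features(seg)["tendency"]  # 14.5 - 254.5 = -240
#' @export
summary_features <- function(seg) {
  stopifnot(inherits(seg, "al_segment"), inherits(seg$data, "al_timeseries"))
  stream_stats(seg$data$t, seg$data$v, seg$window)
}

ratio_floor <- function(num, den, eps = 1e-12) {
  floored <- sum(den < eps)
  out <- num / pmax(den, eps)
  attr(out, "n_floored") <- floored
  out
}

#' Low-beta-to-alpha ratio series (BLA)
#'
#' Pointwise `beta_low / alpha` at one electrode, an engagement-type index.
#' The denominator is floored at `eps` to keep the ratio finite when the
#' device reports zero alpha power; the number of floored samples is attached
#' as attribute `n_floored`.
#'
#' @param bp An `al_bandpower`.
#' @param site Electrode, one of `EEG_SITES`.
#' @param eps Denominator floor (default 1e-12).
#' @return An `al_timeseries`.
#' @export
bla_series <- function(bp, site, eps = 1e-12) {
  site <- match.arg(site, EEG_SITES)
  num <- bp$power[, paste0(site, "_beta_low")]
  den <- bp$power[, paste0(site, "_alpha")]
  r <- ratio_floor(num, den, eps)
  out <- timeseries(bp$t, as.numeric(r), bp$nominal_rate)
  attr(out, "n_floored") <- attr(r, "n_floored")
  out
}

#' Engagement index series (beta over theta plus alpha)
#'
#' Pointwise `(beta_low + beta_high) / (theta + alpha)` at one electrode, the
#' classic task-engagement index. The device reports no unified beta band, so
#' the numerator is the sum of its two beta bands. Denominator flooring as in
#' [bla_series()].
#'
#' @inheritParams bla_series
#' @return An `al_timeseries`.
#' @export
nasa_series <- function(bp, site, eps = 1e-12) {
  site <- match.arg(site, EEG_SITES)
  num <- bp$power[, paste0(site, "_beta_low")] + bp$power[, paste0(site, "_beta_high")]
  den <- bp$power[, paste0(site, "_theta")] + bp$power[, paste0(site, "_alpha")]
  r <- ratio_floor(num, den, eps)
  out <- timeseries(bp$t, as.numeric(r), bp$nominal_rate)
  attr(out, "n_floored") <- attr(r, "n_floored")
  out
}

#' Hemispheric laterality series
#'
#' Pointwise left-minus-right band-power difference per band: temporal axis
#' `T7 - T8`, anterior-frontal axis `AF3 - AF4`.
#'
#' @param bp An `al_bandpower`.
#' @param axis `"T"` (temporal) or `"AF"` (anterior-frontal).
#' @param band Band, one of `EEG_BANDS`.
#' @return An `al_timeseries`.
#' @export
lateral_series <- function(bp, axis = c("T", "AF"), band) {
  axis <- match.arg(axis)
  band <- match.arg(band, EEG_BANDS)
  left <- if (axis == "T") "T7" else "AF3"
  right <- if (axis == "T") "T8" else "AF4"
  v <- bp$power[, paste(left, band, sep = "_")] - bp$power[, paste(right, band, sep = "_")]
  timeseries(bp$t, v, bp$nominal_rate)
}

# All 45 EEG-derived streams of a band-power set, as a named value matrix
# sharing bp$t: 25 site-band streams, 5 BLA, 5 NASA, 5 lateral-T, 5 lateral-AF.
eeg_derived_matrix <- function(bp, eps = 1e-12) {
  n <- length(bp$t)
  cols <- eeg_stream_names()
  m <- matrix(NA_real_, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  for (s in EEG_SITES) for (b in EEG_BANDS) {
    m[, paste(s, toupper(b), sep = "_")] <- bp$power[, paste(s, b, sep = "_")]
  }
  for (s in EEG_SITES) {
    m[, paste0("bla_", s)] <- bla_series(bp, s, eps)$v
    m[, paste0("nasa_", s)] <- nasa_series(bp, s, eps)$v
  }
  for (b in EEG_BANDS) {
    m[, paste0("lateral_T_", toupper(b))] <- lateral_series(bp, "T", b)$v
    m[, paste0("lateral_AF_", toupper(b))] <- lateral_series(bp, "AF", b)$v
  }
  m
}

#' Names of the 45 EEG-derived streams
#' @return Character vector: `"<SITE>_<BAND>"` (25), `"bla_<SITE>"` (5),
#'   `"nasa_<SITE>"` (5), `"lateral_T_<BAND>"` (5), `"lateral_AF_<BAND>"` (5).
#' @export
eeg_stream_names <- function() {
  c(as.vector(t(outer(EEG_SITES, toupper(EEG_BANDS), paste, sep = "_"))),
    paste0("bla_", EEG_SITES), paste0("nasa_", EEG_SITES),
    paste0("lateral_T_", toupper(EEG_BANDS)),
    paste0("lateral_AF_", toupper(EEG_BANDS)))
}

#' EEG feature vector of a segment: 315 named features
#'
#' The 7 summary statistics applied to each of the 45 derived streams
#' (25 site-band power streams, 5 BLA ratios, 5 engagement indices, 5
#' temporal and 5 anterior-frontal laterality series): `7 * 45 = 315`
#' features, named `<stream>_<stat>` (e.g. `T7_GAMMA_median`,
#' `nasa_AF4_median`, `lateral_T_BETA_HIGH_median`, `bla_T7_min`). Missing
#' statistics (empty segment, empty tendency end-window) stay `NA` — they are
#' flagged, never dropped.
#'
#' @param seg An `al_segment` whose `$data` is an `al_bandpower`.
#' @param eps Ratio denominator floor.
#' @return Named numeric vector of length 315.
#' @export
eeg_feature_vector <- function(seg, eps = 1e-12) {
  stopifnot(inherits(seg, "al_segment"), inherits(seg$data, "al_bandpower"))
  bp <- seg$data
  m <- eeg_derived_matrix(bp, eps)
  out <- numeric(0)
  for (j in colnames(m)) {
    st <- stream_stats(bp$t, m[, j], seg$window)
    names(st) <- paste(j, FEATURE_STATS, sep = "_")
    out <- c(out, st)
  }
  out
}

#' EDA feature vector of a segment: 7 named features
#'
#' The 7 summary statistics of the galvanic-skin-resistance stream, named
#' `GSR_<stat>`.
#'
#' @param seg An `al_segment` whose `$data` is an EDA `al_timeseries`.
#' @return Named numeric vector of length 7.
#' @export
eda_feature_vector <- function(seg) {
  st <- summary_features(seg)
  names(st) <- paste("GSR", FEATURE_STATS, sep = "_")
  st
}

#' Parse a feature name back into (stream, stat)
#'
#' Inverse of the naming scheme used by [eeg_feature_vector()] and
#' [eda_feature_vector()]; every generated feature name parses back uniquely.
#'
#' @param name Feature name, e.g. `"lateral_T_BETA_HIGH_median"`.
#' @return List with elements `stream` and `stat`.
#' @export
parse_feature_name <- function(name) {
  stat <- sub("^.*_", "", name)
  if (!stat %in% FEATURE_STATS) {
    stop("parse_feature_name: unknown stat suffix in ", name, call. = FALSE)
  }
  list(stream = sub(paste0("_", stat, "$"), "", name), stat = stat)
}

#' Per-session feature table
#'
#' Computes the feature rows a session contributes to the learning problem:
#' at `level = "process"`, one row per experience sample (13 in the standard
#' design) from the masked 270 s segment preceding each alarm; at
#' `level = "outcome"`, a single row from the masked whole session.
#'
#' @param sess An `al_session`.
#' @param sensor `"eeg"` (315 features) or `"eda"` (7 features).
#' @param level `"process"` or `"outcome"`.
#' @param eps Ratio denominator floor (EEG only).
#' @return `data.frame` with columns `proband_id`, `sample_index` (0 for
#'   outcome level), `coverage`, `flagged`, then the named features.
#' @export
session_features <- function(sess, sensor = c("eeg", "eda"),
                             level = c("process", "outcome"), eps = 1e-12) {
  stopifnot(inherits(sess, "al_session"))
  sensor <- match.arg(sensor)
  level <- match.arg(level)
  x <- if (sensor == "eeg") sess$band_power else sess$eda
  fv <- function(seg) {
    if (sensor == "eeg") eeg_feature_vector(seg, eps) else eda_feature_vector(seg)
  }
  segs <- if (level == "outcome") {
    list(whole_session(x, sess$schedule))
  } else {
    segment_preceding(mask_response_windows(x, sess$schedule), sess$schedule)
  }
  rows <- lapply(segs, fv)
  feat <- do.call(rbind, rows)
  data.frame(
    proband_id = sess$proband_id,
    sample_index = vapply(segs, `[[`, integer(1), "index"),
    coverage = vapply(segs, `[[`, numeric(1), "coverage"),
    flagged = vapply(segs, `[[`, logical(1), "flagged"),
    feat,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Stack per-session feature tables for a cohort
#'
#' @param sessions List of `al_session`.
#' @inheritParams session_features
#' @param drop_flagged Drop rows whose segment coverage is below 0.5
#'   (default `FALSE`: flagged rows are retained but marked).
#' @return `data.frame` as in [session_features()], one block per session.
#' @export
cohort_features <- function(sessions, sensor = c("eeg", "eda"),
                            level = c("process", "outcome"),
                            eps = 1e-12, drop_flagged = FALSE) {
  tab <- do.call(rbind, lapply(sessions, session_features,
                               sensor = sensor, level = level, eps = eps))
  if (drop_flagged) tab <- tab[!tab$flagged, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write / read a feature table as TSV
#' @param tab Feature table from [cohort_features()].
#' @param path TSV path.
#' @return `write_feature_table`: invisibly `path`; `read_feature_table`: the
#'   table.
#' @export
write_feature_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"), check.names = FALSE)
}
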