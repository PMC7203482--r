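#' Experience-sampling scale names
#' @export
ESM_SCALES <- c("interest", "energy", "valence", "focus", "tension")

#' Experience-sample set
#'
#' The in-task self-reports: one row per alarm (13 in the standard design),
#' one column per bipolar slider scale, values on the slider range
#' `[-4000, 4000]`. An entry is missing exactly when the corresponding alarm
#' got no valid answer.
#'
#' @param values Numeric matrix, alarms x 5 scales (columns named as
#'   `ESM_SCALES`); `NA` for missing answers.
#' @param schedule Optional `al_schedule`; if given, missingness must match
#'   `!schedule$valid` row-wise.
#' @return Object of class `al_samples` (the validated matrix).
#' @export
experience_samples <- function(values, schedule = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- NULL
  if (is.null(colnames(values)) || !identical(colnames(values), ESM_SCALES)) {
    stop("experience_samples: columns must be ", paste(ESM_SCALES, collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(values) > 4000, na.rm = TRUE)) {
    stop("experience_samples: slider values must lie in [-4000, 4000]", call. = FALSE)
  }
  if (!is.null(schedule)) {
    if (nrow(values) != length(schedule$alarms)) {
      stop("experience_samples: one row per alarm required", call. = FALSE)
    }
    row_missing <- apply(values, 1L, function(r) all(is.na(r)))
    if (any(row_missing != !schedule$valid)) {
      stop("experience_samples: missing rows must match invalid alarms", call. = FALSE)
    }
  }
  structure(values, class = c("al_samples", "matrix"))
}

#' Outcome questionnaire set
#'
#' Post-session questionnaire scales. Each scale carries its item-response
#' matrix (probands x items, ordinal responses) and the derived scale score,
#' the mean of the items. Item matrices with at least 2 items support
#' reliability estimation via [cronbach_alpha()].
#'
#' @param items Named list of numeric matrices (probands x items), one per
#'   scale; all matrices must have the same row count and >= 2 columns.
#' @return Object of class `al_outcomes`: list with `items` and `scores`
#'   (probands x scales matrix of item means).
#' @export
outcome_set <- function(items) {
  if (!length(items) || is.null(names(items)) || any(!nzchar(names(items)))) {
    stop("outcome_set: `items` must be a non-empty named list", call. = FALSE)
  }
  n <- unique(vapply(items, nrow, integer(1)))
  if (length(n) != 1L) {
    stop("outcome_set: all scales must cover the same probands", call. = FALSE)
  }
  if (any(vapply(items, ncol, integer(1)) < 2L)) {
    stop("outcome_set: scales need >= 2 items for reliability", call. = FALSE)
  }
  scores <- vapply(items, rowMeans, numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1L, dimnames = list(NULL, names(items)))
  structure(list(items = items, scores = scores), class = "al_outcomes")
}

#' A proband's recording session
#'
#' Bundles everything recorded for one participant: the 25 band-power
#' streams, the EDA stream, the alarm schedule with response windows, and the
#' experience-sample matrix. All streams must lie within
#' `[0, session_length]` and the sample matrix must be consistent with the
#' schedule.
#'
#' @param proband_id Participant identifier (coerced to character).
#' @param band_power An `al_bandpower`.
#' @param eda An EDA `al_timeseries` (see [eda_stream()]).
#' @param schedule An `al_schedule`.
#' @param samples An `al_samples` (or plain matrix, validated here).
#' @return Object of class `al_session`.
#' @export
session <- function(proband_id, band_power, eda, schedule, samples) {
  stopifnot(inherits(band_power, "al_bandpower"),
            inherits(eda, "al_timeseries"),
            inherits(schedule, "al_schedule"))
  samples <- experience_samples(unclass(samples), schedule)
  L <- schedule$session_length
  for (tt in list(band_power$t, eda$t)) {
    if (length(tt) && (min(tt) < 0 || max(tt) > L)) {
      stop("session: streams must span [0, session_length]", call. = FALSE)
    }
  }
  structure(list(proband_id = as.character(proband_id),
                 band_power = band_power, eda = eda,
                 schedule = schedule, samples = samples),
            class = "al_session")
}

#' @export
print.al_session <- function(x, ...) {
  cat(sprintf("<al_session> proband %s: %d band-power frames, %d EDA samples, %d/%d valid answers\n",
              x$proband_id, length(x$band_power$t), length(x$eda$t),
              sum(x$schedule$valid), length(x$schedule$alarms)))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

# Full-precision decimal serialization: %.17g round-trips IEEE doubles
# bit-exactly through fread's parser.
fmt_full <- function(x) sprintf("%.17g", x)

write_stream_csv <- function(t, v, path) {
  dt <- data.table::data.table(t = fmt_full(t), v = fmt_full(v))
  data.table::fwrite(dt, path)
}

read_stream_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(numeric = c("t", "v")))
  if (!all(c("t", "v") %in% names(dt))) {
    stop("session format error: stream CSV needs columns t,v: ", path, call. = FALSE)
  }
  dt
}

#' Write a session to a directory
#'
#' Layout: `band_power.csv` (long format `t,electrode,band,v`), `eda.csv`
#' (`t,v`) and `session.json` (proband id, schedule, response windows, slider
#' answers, nominal rates). Numeric values are serialized at full decimal
#' precision so that `read_session(write_session(s)) == s` bit-exactly.
#'
#' @param sess An `al_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(sess, dir) {
  stopifnot(inherits(sess, "al_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bp <- sess$band_power
  nm <- colnames(bp$power)
  # band names contain "_" (beta_low); split on the first separator only
  site <- sub("_.*$", "", nm)
  band <- sub("^[^_]+_", "", nm)
  long <- data.table::data.table(
    t = rep(fmt_full(bp$t), times = length(nm)),
    electrode = rep(site, each = length(bp$t)),
    band = rep(band, each = length(bp$t)),
    v = fmt_full(as.vector(bp$power))
  )
  p_bp <- file.path(dir, "band_power.csv")
  data.table::fwrite(long, p_bp)
  p_eda <- file.path(dir, "eda.csv")
  write_stream_csv(sess$eda$t, sess$eda$v, p_eda)
  sch <- sess$schedule
  meta <- list(
    proband_id = sess$proband_id,
    schedule = list(
      session_length = sch$session_length, interval = sch$interval,
      response_limit = sch$response_limit, alarms = sch$alarms,
      resp_start = sch$resp_start, resp_end = sch$resp_end, valid = sch$valid
    ),
    samples = apply(unclass(sess$samples), 1L, as.list, simplify = FALSE),
    rates = list(band_power = bp$nominal_rate, eda = sess$eda$nominal_rate)
  )
  p_meta <- file.path(dir, "session.json")
  # digits = I(17): 17 significant digits, the full IEEE round-trip precision
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(c(band_power = p_bp, eda = p_eda, meta = p_meta))
}

#' Read a session from a directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return An `al_session`.
#' @export
read_session <- function(dir) {
  p_bp <- file.path(dir, "band_power.csv")
  p_eda <- file.path(dir, "eda.csv")
  p_meta <- file.path(dir, "session.json")
  missing <- !file.exists(c(p_bp, p_eda, p_meta))
  if (any(missing)) {
    stop("incomplete session: missing ",
         paste(basename(c(p_bp, p_eda, p_meta))[missing], collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(p_meta, simplifyVector = TRUE)

  long <- data.table::fread(p_bp, colClasses = list(
    numeric = c("t", "v"), character = c("electrode", "band")))
  if (!all(c("t", "electrode", "band", "v") %in% names(long))) {
    stop("session format error: band_power.csv needs columns t,electrode,band,v",
         call. = FALSE)
  }
  key <- paste(long$electrode, long$band, sep = "_")
  streams <- split(seq_len(nrow(long)), key)
  expected <- bp_stream_names()
  if (!setequal(names(streams), expected)) {
    stop("incomplete session: band_power.csv must contain all 25 streams",
         call. = FALSE)
  }
  t_ref <- long$t[streams[[expected[1L]]]]
  if (length(t_ref) > 1L && any(diff(t_ref) <= 0)) {
    stop("session format error: non-monotone timestamps in band_power.csv",
         call. = FALSE)
  }
  power <- matrix(NA_real_, nrow = length(t_ref), ncol = length(expected),
                  dimnames = list(NULL, expected))
  for (s in expected) {
    idx <- streams[[s]]
    if (length(idx) != length(t_ref) || !identical(long$t[idx], t_ref)) {
      stop("session format error: band-power streams have unequal timestamps",
           call. = FALSE)
    }
    power[, s] <- long$v[idx]
  }
  bp <- bandpower_set(t_ref, power, nominal_rate = meta$rates$band_power)

  eda_dt <- read_stream_csv(p_eda)
  if (nrow(eda_dt) > 1L && any(diff(eda_dt$t) <= 0)) {
    stop("session format error: non-monotone timestamps in eda.csv", call. = FALSE)
  }
  eda <- eda_stream(eda_dt$t, eda_dt$v, nominal_rate = meta$rates$eda)

  sch <- build_schedule(meta$schedule$session_length, meta$schedule$interval,
                        meta$schedule$response_limit)
  sch$resp_start <- as.numeric(meta$schedule$resp_start)
  sch$resp_end <- as.numeric(meta$schedule$resp_end)
  sch$valid <- as.logical(meta$schedule$valid)

  smp <- if (is.data.frame(meta$samples)) {
    m <- as.matrix(meta$samples[, ESM_SCALES, drop = FALSE])
    storage.mode(m) <- "double"
    m
  } else {
    do.call(rbind, lapply(meta$samples, function(r) {
      vapply(ESM_SCALES, function(s) {
        x <- r[[s]]
        if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
      }, numeric(1))
    }))
  }
  session(meta$proband_id, bp, eda, sch, smp)
}

#' Write / read an outcome set as JSON
#' @param out An `al_outcomes`.
#' @param path JSON file path.
#' @return `write_outcomes`: invisibly `path`; `read_outcomes`: an
#'   `al_outcomes`.
#' @export
write_outcomes <- function(out, path) {
  stopifnot(inherits(out, "al_outcomes"))
  jsonlite::write_json(lapply(out$items, unname), path, auto_unbox = FALSE,
                       digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  outcome_set(lapply(raw, function(m) matrix(as.numeric(m), nrow = nrow(m))))
}
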