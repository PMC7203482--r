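#' Spectral configuration for on-device band-power computation
#'
#' Mirrors the consumer headset's documented preprocessing: raw EEG sampled at
#' 128 Hz, short-time FFT over a 2 s Hann-tapered window, power summed per
#' canonical band, frames emitted every `step` samples. The default step of 16
#' samples yields the 8 Hz output rate the downstream analysis uses; the
#' vendor text also mentions a 125-sample step (about 1 Hz), available by
#' overriding `step`.
#'
#' @param sample_rate Raw sampling rate in Hz (default 128).
#' @param window Window length in seconds (default 2); `window * sample_rate`
#'   must be a whole number of samples.
#' @param step Hop size in samples (default 16, i.e. 8 Hz output at 128 Hz).
#' @param bands Named list of `[low, high)` band edges in Hz (default
#'   [eeg_band_edges()]); edges must lie within `(0, sample_rate/2]`.
#' @return Object of class `al_spectral_config`.
#' @export
spectral_config <- function(sample_rate = 128, window = 2, step = 16,
                            bands = eeg_band_edges()) {
  n_win <- sample_rate * window
  if (abs(n_win - round(n_win)) > 1e-9) {
    stop("spectral_config: window must span an integer number of samples", call. = FALSE)
  }
  if (step < 1) stop("spectral_config: step must be >= 1", call. = FALSE)
  edges <- unlist(bands, use.names = FALSE)
  if (any(edges <= 0) || any(edges > sample_rate / 2)) {
    stop("spectral_config: band edges must lie in (0, sample_rate/2]", call. = FALSE)
  }
  structure(list(sample_rate = sample_rate, window = window,
                 n_window = as.integer(round(n_win)), step = as.integer(step),
                 bands = bands),
            class = "al_spectral_config")
}

# Periodic Hann taper of length n (the standard choice for short-time FFT).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Compute per-band power from raw EEG
#'
#' Slides a Hann-tapered window of `cfg$window` seconds over the raw signal in
#' hops of `cfg$step` samples. For each window position and band, power is the
#' sum of squared FFT magnitudes over the positive-frequency bins whose
#' frequency falls in the band's half-open `[low, high)` interval (0.5 Hz bin
#' resolution at the 2 s / 128 Hz default). Each frame is stamped with the
#' time of the last raw sample in its window, so the output rate is
#' `sample_rate / step`.
#'
#' @param raw An `al_timeseries`, uniformly sampled at `cfg$sample_rate`.
#' @param cfg An `al_spectral_config`.
#' @return Named list of `al_timeseries`, one per band.
#' @examples
#' cfg <- spectral_config()
#' t <- (0:511) / 128
#' tone <- timeseries(t, sin(2 * pi * 10 * t), 128)
#' bp <- compute_band_power(tone, cfg)
#' names(bp)
#' @export
compute_band_power <- function(raw, cfg = spectral_config()) {
  stopifnot(inherits(raw, "al_timeseries"), inherits(cfg, "al_spectral_config"))
  N <- cfg$n_window
  x <- raw$v
  if (length(x) < N) {
    stop("compute_band_power: insufficient data (need >= one window of ",
         N, " samples)", call. = FALSE)
  }
  starts <- seq.int(1L, length(x) - N + 1L, by = cfg$step)
  taper <- hann_window(N)
  freqs <- (0:(N - 1)) * cfg$sample_rate / N
  bins <- lapply(cfg$bands, function(e) which(freqs >= e[1] & freqs < e[2] & freqs <= cfg$sample_rate / 2))
  # window matrix: N x n_frames, tapered, one FFT per column
  idx <- outer(0:(N - 1L), starts, `+`)
  W <- matrix(x[idx], nrow = N) * taper
  spec <- stats::mvfft(W)
  p <- abs(spec)^2
  out_t <- raw$t[starts + N - 1L]
  rate_out <- cfg$sample_rate / cfg$step
  res <- lapply(bins, function(b) {
    pw <- if (length(b) == 1L) p[b, ] else colSums(p[b, , drop = FALSE])
    timeseries(out_t, pw, rate_out)
  })
  names(res) <- names(cfg$bands)
  res
}

#' Total spectral power of each window (all positive-frequency bins)
#'
#' Companion to [compute_band_power()] for Parseval-style checks: the five
#' canonical bands cover only 4-45 Hz, so their summed power can never exceed
#' this total.
#'
#' @inheritParams compute_band_power
#' @return An `al_timeseries` of total power per frame.
#' @export
total_spectral_power <- function(raw, cfg = spectral_config()) {
  full <- cfg
  full$bands <- list(all = c(cfg$sample_rate / cfg$n_window, cfg$sample_rate / 2))
  compute_band_power(raw, full)$all
}

#' Emulate the headset: 5 raw channels to a 25-stream band-power set
#'
#' Applies [compute_band_power()] to each electrode's raw stream and
#' assembles the aligned `al_bandpower` container.
#'
#' @param raw5 Named list of 5 `al_timeseries` (names `EEG_SITES`), equal
#'   lengths and identical timestamps.
#' @param cfg An `al_spectral_config`.
#' @return An `al_bandpower`.
#' @export
emulate_device <- function(raw5, cfg = spectral_config()) {
  if (!setequal(names(raw5), EEG_SITES)) {
    stop("emulate_device: raw5 must be named by electrode (", paste(EEG_SITES, collapse = ", "), ")",
         call. = FALSE)
  }
  lens <- vapply(raw5, function(s) length(s$t), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("emulate_device: electrode streams differ in length (alignment error)",
         call. = FALSE)
  }
  per_site <- lapply(raw5[EEG_SITES], compute_band_power, cfg = cfg)
  t_out <- per_site[[1L]][[1L]]$t
  power <- matrix(NA_real_, nrow = length(t_out), ncol = 25L,
                  dimnames = list(NULL, bp_stream_names()))
  for (s in EEG_SITES) for (b in EEG_BANDS) {
    power[, paste(s, b, sep = "_")] <- per_site[[s]][[b]]$v
  }
  bandpower_set(t_out, power, nominal_rate = cfg$sample_rate / cfg$step)
}
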