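# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A band-power set with deterministic values: stream (site, band) holds
# `base + site_offset` everywhere, on a uniform 8 Hz grid.
make_flat_bp <- function(n = 80, rate = 8,
                         levels = c(theta = 4, alpha = 3, beta_low = 2,
                                    beta_high = 1.5, gamma = 1),
                         site_offset = c(AF3 = 0, AF4 = 0, T7 = 0, T8 = 0, Pz = 0)) {
  t <- (seq_len(n) - 1) / rate
  power <- matrix(NA_real_, n, 25, dimnames = list(NULL, bp_stream_names()))
  for (s in EEG_SITES) for (b in EEG_BANDS) {
    power[, paste(s, b, sep = "_")] <- levels[[b]] + site_offset[[s]]
  }
  bandpower_set(t, power, rate)
}

# Wrap a stream into a whole-window segment without any masking.
make_segment <- function(ts, start, end, index = 1L) {
  keep <- ts$t >= start & ts$t < end
  data <- timeseries(ts$t[keep], ts$v[keep], ts$nominal_rate)
  structure(list(index = index, window = c(start, end), data = data,
                 coverage = 1, flagged = FALSE),
            class = "al_segment")
}

make_bp_segment <- function(bp, start = min(bp$t), end = max(bp$t) + 1e-9,
                            index = 0L) {
  keep <- bp$t >= start & bp$t < end
  data <- bandpower_set(bp$t[keep], bp$power[keep, , drop = FALSE], bp$nominal_rate)
  structure(list(index = index, window = c(start, end), data = data,
                 coverage = 1, flagged = FALSE),
            class = "al_segment")
}

# A small fully valid session with lognormal band power and positive GSR.
make_session <- function(id = "p01", session_length = 540, interval = 270,
                         seed = 1) {
  set.seed(seed)
  rate_bp <- 8; rate_eda <- 5
  t_bp <- seq(0, by = 1 / rate_bp, length.out = session_length * rate_bp)
  power <- matrix(exp(rnorm(length(t_bp) * 25, 0, 0.3)),
                  ncol = 25, dimnames = list(NULL, bp_stream_names()))
  bp <- bandpower_set(t_bp, power, rate_bp)
  t_eda <- seq(0, by = 1 / rate_eda, length.out = session_length * rate_eda)
  eda <- eda_stream(t_eda, 300 * exp(rnorm(length(t_eda), 0, 0.05)), rate_eda)
  sch <- build_schedule(session_length, interval, 60)
  k <- length(sch$alarms)
  sch <- register_responses(sch, runif(k, 10, 25))
  sliders <- matrix(runif(k * 5, -4000, 4000), nrow = k,
                    dimnames = list(NULL, ESM_SCALES))
  session(id, bp, eda, sch, sliders)
}

# Independent brute-force DFT: direct O(N^2) sum, no FFT.
brute_dft_power <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  sapply(k, function(kk) {
    ang <- -2 * pi * kk * (0:(N - 1)) / N
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))^2
  })
}

# Independent numeric minimizer of the ridge loss on the standardized design:
# BFGS on ||y - Zw - b||^2 + lambda ||w||^2.
ridge_bfgs_oracle <- function(X, y, lambda) {
  n <- nrow(X)
  Z <- scale(X)
  Z[, apply(X, 2, sd) == 0] <- 0
  obj <- function(par) {
    w <- par[-length(par)]; b <- par[length(par)]
    sum((y - Z %*% w - b)^2) + lambda * sum(w^2)
  }
  gr <- function(par) {
    w <- par[-length(par)]; b <- par[length(par)]
    r <- as.numeric(y - Z %*% w - b)
    c(-2 * as.numeric(crossprod(Z, r)) + 2 * lambda * w, -2 * sum(r))
  }
  o <- optim(rep(0, ncol(X) + 1), obj, gr, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-16))
  list(w = o$par[-length(o$par)], intercept = o$par[length(o$par)])
}
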