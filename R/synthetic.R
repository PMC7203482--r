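#' Synthetic cohort generator configuration
#'
#' Defines the study conditions a generated cohort emulates: 3600 s learning
#' sessions, vibration alarms every 270 s (13 experience samples), response
#' times truncated-normal(16.36, 7.36) on (0, 60], band power at 8 Hz over 5
#' electrodes x 5 bands, GSR at 5 Hz, bipolar sliders on [-4000, 4000], and 12
#' outcome scales with the study's reliabilities. Each proband carries latent
#' traits (one activation trait per electrode site plus a general affect
#' trait); a slow mean-reverting affect state drives band power, EDA and the
#' sliders; outcome scores derive from the traits through a one-factor item
#' model that hits each scale's target Cronbach's alpha.
#'
#' @param n_probands Cohort size.
#' @param seed Integer seed (mandatory; same seed, same cohort).
#' @param session_length,interval,response_limit Session design, seconds.
#' @param response_mean,response_sd Response-time distribution (s), truncated
#'   to (0, `response_limit`].
#' @param p_miss Probability an alarm gets no answer (default 0).
#' @param bp_rate,eda_rate Sensor rates, Hz.
#' @param band_baseline Baseline band-power level per band (device units).
#' @param noise_sdlog Lognormal band-power noise sd (log scale).
#' @param state_tau,state_sd Mean-reversion time (s) and stationary sd of the
#'   latent affect state (1 Hz discrete process).
#' @param state_level_gain Trait-to-state: stationary state mean is
#'   `state_level_gain * g`.
#' @param state_gain,trait_gain Log-band-power gains of the state and of the
#'   site activation trait.
#' @param slider_load Named loadings (slider units per state unit) for the 5
#'   scales; tension loads negatively.
#' @param slider_noise Slider noise sd (slider units), applied before
#'   clipping to [-4000, 4000].
#' @param eda_base,eda_base_sdlog Baseline skin resistance (kOhm) and its
#'   between-proband lognormal sd.
#' @param eda_drift Log-scale tonic drift over the whole session.
#' @param eda_state_gain Log-GSR per state unit (negative: arousal lowers
#'   resistance).
#' @param eda_noise_sdlog Lognormal GSR noise sd.
#' @param outcome_scales data.frame with columns `name`, `n_items`, `alpha`
#'   (target reliability in (0, 1)), `load_g` (loading of the general affect
#'   trait); default: the 12 study scales.
#' @param item_levels,item_mean,item_sd Ordinal item scale (0 ..
#'   `item_levels - 1`), latent item mean and sd before rounding.
#' @param t7_effect Strength in [0, 1] of the planted negative dependence of
#'   the intrinsic-motivation outcome on the T7 activation trait (see
#'   [plant_t7_effect()]).
#' @return Object of class `al_generator_config`.
#' @export
generator_config <- function(n_probands, seed,
                             session_length = 3600, interval = 270,
                             response_limit = 60,
                             response_mean = 16.36, response_sd = 7.36,
                             p_miss = 0,
                             bp_rate = 8, eda_rate = 5,
                             band_baseline = c(theta = 40, alpha = 30,
                                               beta_low = 20, beta_high = 15,
                                               gamma = 10),
                             noise_sdlog = 0.4,
                             state_tau = 120, state_sd = 1,
                             state_level_gain = 0.5,
                             state_gain = 0.3, trait_gain = 0.5,
                             slider_load = c(interest = 1500, energy = 1200,
                                             valence = 1300, focus = 1000,
                                             tension = -1100),
                             slider_noise = 900,
                             eda_base = 300, eda_base_sdlog = 0.3,
                             eda_drift = -0.2, eda_state_gain = -0.1,
                             eda_noise_sdlog = 0.05,
                             outcome_scales = default_outcome_scales(),
                             item_levels = 5L, item_mean = 2, item_sd = 0.9,
                             t7_effect = 0) {
  if (missing(seed)) stop("generator_config: `seed` is mandatory", call. = FALSE)
  if (n_probands < 1L) stop("generator_config: need n_probands >= 1", call. = FALSE)
  if (any(outcome_scales$alpha >= 1 | outcome_scales$alpha <= 0)) {
    stop("generator_config: infeasible reliability target (alpha must be in (0, 1))",
         call. = FALSE)
  }
  stopifnot(all(c("name", "n_items", "alpha", "load_g") %in% names(outcome_scales)),
            all(outcome_scales$n_items >= 2L),
            noise_sdlog >= 0, state_sd >= 0, slider_noise >= 0,
            eda_base_sdlog >= 0, eda_noise_sdlog >= 0,
            t7_effect >= 0, t7_effect <= 1,
            identical(sort(names(slider_load)), sort(ESM_SCALES)),
            identical(sort(names(band_baseline)), sort(EEG_BANDS)))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "al_generator_config")
}

#' The 12 outcome scales of the study design, with target reliabilities
#'
#' Six self-determination regulation scales, the two motivation/workload
#' scales and the four mood scales, with the reliabilities the study reports
#' and 8 items each. `intrinsic_motivation` is the scale the planted T7
#' effect targets.
#' @return data.frame with `name`, `n_items`, `alpha`, `load_g`.
#' @export
default_outcome_scales <- function() {
  data.frame(
    name = c("amotivation", "external_motivation", "introjected_motivation",
             "identified_motivation", "intrinsic_motivation_sdt", "interest",
             "intrinsic_motivation", "workload", "tense_arousal",
             "anger_frustration", "energetic_arousal", "hedonic_tone"),
    n_items = 8L,
    alpha = c(0.68, 0.61, 0.38, 0.60, 0.69, 0.80,
              0.81, 0.37, 0.89, 0.87, 0.90, 0.88),
    load_g = 0.5,
    stringsAsFactors = FALSE
  )
}

#' Plant a recoverable T7 -> intrinsic-motivation effect
#'
#' Adds a negative dependence of the `intrinsic_motivation` outcome factor on
#' the proband's T7 activation trait — the trait that multiplies all five
#' band-power streams at the left temporal electrode — leaving every other
#' site untouched. At `strength` 0 the generated cohort is bit-identical to
#' the unplanted one for the same seed.
#'
#' @param cfg An `al_generator_config`.
#' @param strength Effect strength in [0, 1] (correlation scale).
#' @return The modified config.
#' @export
plant_t7_effect <- function(cfg, strength) {
  stopifnot(inherits(cfg, "al_generator_config"),
            strength >= 0, strength <= 1)
  cfg$t7_effect <- strength
  cfg
}

# Truncated-normal response durations on (0, limit] by rejection.
draw_response_times <- function(n, mean, sd, limit) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0 & x <= limit])
  }
  out[seq_len(n)]
}

# Latent affect state: discrete-time mean-reverting (AR(1)) process at 1 Hz
# with stationary mean `mu`, stationary sd `sd` and relaxation time `tau` s.
simulate_state <- function(length_s, tau, sd, mu) {
  n <- length_s + 1L
  phi <- exp(-1 / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  eps <- stats::rnorm(n, 0, 1)
  x[1L] <- mu + sd * eps[1L]
  for (i in 2:n) x[i] <- mu + phi * (x[i - 1L] - mu) + innov_sd * eps[i]
  x
}

# One proband's session given their traits. Consumes RNG in a fixed order.
gen_proband_session <- function(cfg, id, a_site, g) {
  L <- cfg$session_length
  state1 <- simulate_state(L, cfg$state_tau, cfg$state_sd,
                           mu = cfg$state_level_gain * g)
  t_state <- 0:L

  t_bp <- seq(0, by = 1 / cfg$bp_rate, length.out = L * cfg$bp_rate)
  s_bp <- stats::approx(t_state, state1, xout = t_bp)$y
  n_bp <- length(t_bp)
  power <- matrix(NA_real_, nrow = n_bp, ncol = 25L,
                  dimnames = list(NULL, bp_stream_names()))
  for (s in EEG_SITES) for (b in EEG_BANDS) {
    noise <- if (cfg$noise_sdlog > 0) stats::rnorm(n_bp, 0, cfg$noise_sdlog) else numeric(n_bp)
    power[, paste(s, b, sep = "_")] <-
      cfg$band_baseline[[b]] *
      exp(cfg$state_gain * s_bp + cfg$trait_gain * a_site[[s]] + noise)
  }
  bp <- bandpower_set(t_bp, power, cfg$bp_rate)

  t_eda <- seq(0, by = 1 / cfg$eda_rate, length.out = L * cfg$eda_rate)
  s_eda <- stats::approx(t_state, state1, xout = t_eda)$y
  base_i <- cfg$eda_base * exp(stats::rnorm(1, 0, cfg$eda_base_sdlog))
  eda_noise <- if (cfg$eda_noise_sdlog > 0) stats::rnorm(length(t_eda), 0, cfg$eda_noise_sdlog) else numeric(length(t_eda))
  gsr <- base_i * exp(cfg$eda_drift * t_eda / L + cfg$eda_state_gain * s_eda + eda_noise)
  eda <- eda_stream(t_eda, gsr, cfg$eda_rate)

  sch <- build_schedule(L, cfg$interval, cfg$response_limit)
  k <- length(sch$alarms)
  dur <- draw_response_times(k, cfg$response_mean, cfg$response_sd, cfg$response_limit)
  missed <- stats::runif(k) < cfg$p_miss
  dur[missed] <- NA_real_
  sch <- register_responses(sch, dur)

  alarm_state <- state1[sch$alarms + 1L]   # alarms fall on whole seconds
  sliders <- matrix(NA_real_, nrow = k, ncol = 5L,
                    dimnames = list(NULL, ESM_SCALES))
  noise <- matrix(stats::rnorm(k * 5L, 0, cfg$slider_noise), nrow = k)
  for (j in seq_along(ESM_SCALES)) {
    v <- cfg$slider_load[[ESM_SCALES[j]]] * alarm_state + noise[, j]
    sliders[, j] <- pmin(4000, pmax(-4000, v))
  }
  sliders[!sch$valid, ] <- NA_real_

  list(session = session(id, bp, eda, sch, sliders),
       state = state1, alarm_state = alarm_state)
}

# Outcome item matrices from a one-factor model per scale. The target
# inter-item correlation implied by alpha is pre-inflated by the analytic
# rounding-attenuation factor (s^2 + 1/12)/s^2 so that measured alpha on the
# rounded 0..(levels-1) items still hits the target.
gen_outcomes <- function(cfg, traits) {
  n <- nrow(traits)
  scales <- cfg$outcome_scales
  items <- list()
  factors <- matrix(NA_real_, nrow = n, ncol = nrow(scales),
                    dimnames = list(NULL, scales$name))
  a_t7 <- traits[, "T7"]
  g <- traits[, "g"]
  s <- cfg$t7_effect
  for (r in seq_len(nrow(scales))) {
    nm <- scales$name[r]
    k <- scales$n_items[r]
    lam <- scales$load_g[r]
    u <- stats::rnorm(n)
    h <- lam * g + sqrt(1 - lam^2) * u
    f <- if (nm == "intrinsic_motivation") {
      -s * a_t7 + sqrt(1 - s^2) * h
    } else h
    factors[, r] <- f
    rbar <- scales$alpha[r] / (k - scales$alpha[r] * (k - 1))
    rbar_adj <- min(0.999, rbar * (cfg$item_sd^2 + 1 / 12) / cfg$item_sd^2)
    e <- matrix(stats::rnorm(n * k), nrow = n)
    latent <- cfg$item_mean +
      cfg$item_sd * (sqrt(rbar_adj) * f + sqrt(1 - rbar_adj) * e)
    resp <- pmin(cfg$item_levels - 1L, pmax(0L, round(latent)))
    items[[nm]] <- matrix(resp, nrow = n)
  }
  list(items = items, factors = factors)
}

#' Generate a complete synthetic cohort
#'
#' Draws proband traits, simulates every session (latent affect state, 25
#' band-power streams, GSR, alarm schedule with response windows, slider
#' answers) and the outcome questionnaires, and returns the ground truth
#' alongside so planted effects are recoverable in tests.
#'
#' @param cfg An `al_generator_config`.
#' @param keep_sessions Keep the full sensor sessions in the return value
#'   (default `TRUE`); with `FALSE` only feature-free per-proband summaries
#'   (schedule, sliders) are retained, for memory-light pipelines use
#'   [simulate_study()] instead.
#' @return List with `sessions` (list of `al_session`), `outcomes`
#'   (`al_outcomes`, score rows named by proband), `proband_ids`, and
#'   `truth` (traits, per-proband latent states, alarm states, noiseless
#'   outcome factors).
#' @export
generate_cohort <- function(cfg, keep_sessions = TRUE) {
  stopifnot(inherits(cfg, "al_generator_config"))
  rng <- rng_stream(cfg$seed)
  rng$draw(function() {
    n <- cfg$n_probands
    ids <- sprintf("p%02d", seq_len(n))
    traits <- cbind(matrix(stats::rnorm(n * 5L), nrow = n,
                           dimnames = list(ids, EEG_SITES)),
                    g = stats::rnorm(n))
    sessions <- vector("list", n)
    states <- matrix(NA_real_, nrow = n, ncol = cfg$session_length + 1L,
                     dimnames = list(ids, NULL))
    alarm_states <- NULL
    for (i in seq_len(n)) {
      gp <- gen_proband_session(cfg, ids[i], traits[i, EEG_SITES], traits[i, "g"])
      sessions[[i]] <- gp$session
      states[i, ] <- gp$state
      if (is.null(alarm_states)) {
        alarm_states <- matrix(NA_real_, nrow = n, ncol = length(gp$alarm_state),
                               dimnames = list(ids, NULL))
      }
      alarm_states[i, ] <- gp$alarm_state
    }
    oc <- gen_outcomes(cfg, traits)
    outcomes <- outcome_set(oc$items)
    rownames(outcomes$scores) <- ids
    list(sessions = if (keep_sessions) sessions else NULL,
         outcomes = outcomes, proband_ids = ids,
         truth = list(traits = traits, states = states,
                      alarm_states = alarm_states, factors = oc$factors))
  })
}

#' Simulate a cohort and return its feature tables (memory-light)
#'
#' Generates the cohort proband by proband, computing each session's feature
#' rows and discarding the raw streams immediately. For a given config the
#' features are identical to running [generate_cohort()] followed by
#' [cohort_features()].
#'
#' @param cfg An `al_generator_config`.
#' @param sensor `"eeg"` or `"eda"`.
#' @param level `"process"` or `"outcome"`.
#' @return List with `features` (data.frame), `labels` (process level: alarm
#'   x scale slider matrices per proband; outcome level: the score matrix),
#'   `outcomes` (`al_outcomes`) and `truth`.
#' @export
simulate_study <- function(cfg, sensor = c("eeg", "eda"),
                           level = c("process", "outcome")) {
  stopifnot(inherits(cfg, "al_generator_config"))
  sensor <- match.arg(sensor)
  level <- match.arg(level)
  rng <- rng_stream(cfg$seed)
  rng$draw(function() {
    n <- cfg$n_probands
    ids <- sprintf("p%02d", seq_len(n))
    traits <- cbind(matrix(stats::rnorm(n * 5L), nrow = n,
                           dimnames = list(ids, EEG_SITES)),
                    g = stats::rnorm(n))
    feats <- vector("list", n)
    sliders <- vector("list", n)
    for (i in seq_len(n)) {
      gp <- gen_proband_session(cfg, ids[i], traits[i, EEG_SITES], traits[i, "g"])
      feats[[i]] <- session_features(gp$session, sensor = sensor, level = level)
      sliders[[i]] <- unclass(gp$session$samples)
      rm(gp)
    }
    oc <- gen_outcomes(cfg, traits)
    outcomes <- outcome_set(oc$items)
    rownames(outcomes$scores) <- ids
    names(sliders) <- ids
    list(features = do.call(rbind, feats),
         labels = if (level == "outcome") outcomes$scores else sliders,
         outcomes = outcomes,
         truth = list(traits = traits, factors = oc$factors))
  })
}

#' Write a generated cohort to disk
#'
#' One session directory per proband (see [write_session()]), plus
#' `outcomes.json` and `ground_truth.json`.
#'
#' @param cohort Result of [generate_cohort()] (with sessions kept).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$sessions))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sess in cohort$sessions) {
    write_session(sess, file.path(dir, sess$proband_id))
  }
  write_outcomes(cohort$outcomes, file.path(dir, "outcomes.json"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(proband_ids = cohort$proband_ids,
         traits = truth$traits, alarm_states = truth$alarm_states,
         factors = truth$factors),
    file.path(dir, "ground_truth.json"),
    digits = NA, matrix = "rowmajor")
  invisible(dir)
}
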