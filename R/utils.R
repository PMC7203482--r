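#' @importFrom stats predict
NULL

# Self-contained RNG stream: draws are reproducible from `seed` and do not
# disturb (or depend on) the caller's global RNG state.
rng_stream <- function(seed) {
  genv <- globalenv()
  save_state <- function() get0(".Random.seed", envir = genv, inherits = FALSE)
  restore_state <- function(s) {
    if (is.null(s)) {
      if (!is.null(save_state())) rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", s, envir = genv)
    }
  }
  outer_state <- save_state()
  set.seed(as.integer(seed))
  state <- save_state()
  restore_state(outer_state)

  draw <- function(fn, ...) {
    outer <- save_state()
    restore_state(state)
    out <- fn(...)
    state <<- save_state()
    restore_state(outer)
    out
  }
  list(
    unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    draw = draw
  )
}

# Derive a bounded child seed from a parent seed and an index (keeps every
# seed a valid 32-bit R integer).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
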