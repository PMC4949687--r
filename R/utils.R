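# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package route through this
# so they are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles into [-pi, pi).
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# Wrap angles into [0, 2*pi).
wrap_2pi <- function(x) {
  x %% (2 * pi)
}

stop_if_not_scalar_prob <- function(x, name, closed_upper = FALSE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || !hi_ok) {
    stop(sprintf("`%s` must be a single probability in (0,1%s)",
                 name, if (closed_upper) "]" else ""), call. = FALSE)
  }
  invisible(x)
}
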