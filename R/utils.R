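# internal helpers shared across modules

stop_invalid <- function(msg) abort(msg, class = "trbs_invalid_argument")

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (finite && any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite.", name))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    stop_invalid(sprintf(
      "`%s` must be %s %g.", name, if (strict) "greater than" else "at least", lower
    ))
  }
  invisible(x)
}

# three-point parabolic refinement of a peak on a uniform grid.
# y: values at indices i-1, i, i+1 (typically log-magnitudes); returns the
# sub-grid offset in [-0.5, 0.5] of the vertex relative to the middle point.
parabolic_offset <- function(y) {
  denom <- y[1] - 2 * y[2] + y[3]
  if (!is.finite(denom) || denom >= 0) return(0)
  d <- 0.5 * (y[1] - y[3]) / denom
  max(-0.5, min(0.5, d))
}

# analytic-signal magnitude via the one-sided FFT spectrum (quadrature
# envelope). No installed package exposes this primitive, so it lives here.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# seeded sub-stream draws: a vector of independent child seeds derived from
# one parent seed, stable across platforms (31-bit range for R's RNG API)
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep.int(NA_integer_, n))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
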