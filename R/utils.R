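# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Strict local extrema: strictly greater/less than both immediate
# neighbours. Plateau samples are not extrema; the first point of a plateau
# is taken only when it strictly dominates both neighbours (which a plateau
# interior never does).
local_minima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- x[2:(n - 1)]
  which(core < x[1:(n - 2)] & core < x[3:n]) + 1L
}

local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- x[2:(n - 1)]
  which(core > x[1:(n - 2)] & core > x[3:n]) + 1L
}

# First strict local minimum of x at or after index `from` (1-based).
# Returns NA_integer_ when the search exhausts the signal.
first_min_from <- function(x, from) {
  n <- length(x)
  j <- max(from, 2L)
  while (j + 1L <= n) {
    if (x[j] < x[j - 1L] && x[j] < x[j + 1L]) return(j)
    j <- j + 1L
  }
  NA_integer_
}

first_max_from <- function(x, from) {
  n <- length(x)
  j <- max(from, 2L)
  while (j + 1L <= n) {
    if (x[j] > x[j - 1L] && x[j] > x[j + 1L]) return(j)
    j <- j + 1L
  }
  NA_integer_
}

# Cumulative trapezoidal integral on a uniform grid with spacing h,
# initial value 0.
cumtrapz_uniform <- function(x, h) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum((x[-1] + x[-n]) / 2)) * h
}

# Trapezoidal area under y sampled at x.
trapz_area <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
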