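# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state. The global .Random.seed is restored
# afterwards so generators are pure functions of (parameters, seed) and never
# perturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Gaussian band parameterized by FWHM. `height` form peaks at `height`;
# `area` form integrates to `area`.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gauss_height <- function(x, center, fwhm, height) {
  s <- fwhm_to_sigma(fwhm)
  height * exp(-(x - center)^2 / (2 * s^2))
}

gauss_area <- function(x, center, fwhm, area) {
  s <- fwhm_to_sigma(fwhm)
  area / (s * sqrt(2 * pi)) * exp(-(x - center)^2 / (2 * s^2))
}

# Centered moving average with shrinking windows at the ends, so the output
# has the same length as the input and no NA padding.
moving_average <- function(v, window = 5L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(v[lo:hi])
  }, numeric(1))
}

# Strict interior local extrema of a numeric vector; returns indices.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
}

local_minima <- function(v) local_maxima(-v)

stop_input <- function(...) stop(..., call. = FALSE)
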