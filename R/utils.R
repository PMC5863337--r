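# Internal numeric helpers shared across modules.

#' Evaluate code with a temporarily fixed RNG state
#'
#' Seeds the session RNG, runs `code`, and restores the previous RNG state on
#' exit, so phantom generation is reproducible without clobbering the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Sub-pixel refinement of a discrete extremum by fitting a parabola through
# (i-1, i, i+1). Returns the fractional offset in [-0.5, 0.5]; 0 at the border
# or for a degenerate (flat) triple.
parabolic_offset <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}

# Gaussian kernel with sd `sigma` px, truncated at 3 sigma, normalised.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D Gaussian smoothing with replicated-edge padding.
smooth1d <- function(x, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x)
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + length(x))]
}

# Separable 2-D Gaussian smoothing of a matrix (rows then columns).
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sm <- apply(m, 2L, smooth1d, sigma = sigma)
  t(apply(sm, 1L, smooth1d, sigma = sigma))
}

# Centred moving average of window w (odd), replicated edges.
movavg <- function(x, w = 5L) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  r <- w %/% 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(r + 1L):(r + length(x))]
}

# Signed polygon area by the shoelace formula; `xy` is an n x 2 matrix of an
# open (last point != first) simple polygon.
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

# Central-difference derivative on a (possibly non-uniform) time axis.
central_diff <- function(y, t) {
  n <- length(y)
  stopifnot(n >= 2L, length(t) == n)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  }
  d
}

# Spatially correlated multiplicative speckle field with mean 1 and standard
# deviation `sd`: Rayleigh draws, low-pass filtered to correlation length
# `corr` px, then re-standardised. `sd` = 0 returns a field of ones.
speckle_field <- function(h, w, sd, corr = 1.5) {
  if (sd <= 0) return(matrix(1, h, w))
  sigma0 <- sqrt(2 / pi)   # Rayleigh scale giving unit mean
  raw <- matrix(sigma0 * sqrt(-2 * log(stats::runif(h * w))), h, w)
  sm <- smooth2d(raw, corr)
  s <- stats::sd(sm)
  if (s < .Machine$double.eps) return(matrix(1, h, w))
  1 + sd * (sm - mean(sm)) / s
}

# Clamp numeric data into the 8-bit display range.
clamp255 <- function(x) pmin(pmax(x, 0), 255)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_musecho <- function(msg, class) {
  stop(structure(class = c(class, "musecho_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
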