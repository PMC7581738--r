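#' Fractional Gaussian noise autocovariance
#'
#' Closed-form autocovariance of stationary fractional Gaussian noise (fGn)
#' with Hurst exponent `hurst` and marginal variance `variance`:
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)}
#'
#' @param lag Integer vector of lags (k >= 0).
#' @param hurst Hurst exponent H in (0, 1).
#' @param variance Marginal variance sigma^2 (> 0), signal units squared.
#' @return Numeric vector of autocovariances, one per lag.
#' @examples
#' fgn_autocovariance(0:3, hurst = 0.8)
#' @export
fgn_autocovariance <- function(lag, hurst, variance = 1) {
  check_number(hurst, "hurst", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(variance, "variance", 0, closed_lower = FALSE)
  k <- abs(lag)
  variance / 2 * (abs(k + 1)^(2 * hurst) - 2 * k^(2 * hurst) + abs(k - 1)^(2 * hurst))
}

#' Simulate exact fractional Gaussian noise
#'
#' Draws a stationary Gaussian series whose autocovariance is exactly the fGn
#' form for the requested Hurst exponent, using circulant embedding
#' (Davies-Harte). The method is exact: no truncation or approximation is
#' involved as long as the circulant embedding is non-negative definite, which
#' holds for fGn at all H in (0, 1); should a negative eigenvalue nonetheless
#' arise it is an error unless `allow_approx = TRUE` explicitly permits
#' clipping it to zero.
#'
#' @param n Series length (>= 2).
#' @param hurst Hurst exponent in (0, 1). `hurst = 0.5` gives white noise.
#' @param variance Marginal variance of the series (default 1).
#' @param seed Optional integer seed; the same seed always reproduces the same
#'   series, and `variance` only rescales it (`sqrt(variance) * unit draw`).
#' @param allow_approx Permit clipping of negative embedding eigenvalues
#'   (default `FALSE`: fail loudly instead of silently approximating).
#' @return A tibble with columns `time` (1..n) and `value`.
#' @examples
#' x <- fgn(300, hurst = 0.8, variance = 400, seed = 1)
#' stats::var(x$value)
#' @seealso [white_noise()], [fbm()], [fgn_autocovariance()]
#' @export
fgn <- function(n, hurst, variance = 1, seed = NULL, allow_approx = FALSE) {
  n <- check_count(n, "n", lower = 2L)
  check_number(hurst, "hurst", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(variance, "variance", 0, closed_lower = FALSE)
  values <- sqrt(variance) * fgn_unit(n, hurst, seed, allow_approx)
  tibble(time = seq_len(n), value = values)
}

# Unit-variance fGn via Davies-Harte circulant embedding.
fgn_unit <- function(n, hurst, seed, allow_approx) {
  m <- 2L * (n - 1L)
  if (m < 2L) m <- 2L
  gamma <- fgn_autocovariance(0:(n - 1L), hurst, 1)
  circ <- c(gamma, if (n > 2L) gamma[(n - 1L):2L])
  lambda <- Re(fft(circ))
  if (any(lambda < 0)) {
    worst <- min(lambda)
    # fGn embeddings are provably nonnegative definite; tolerate only
    # floating-point dust unless the caller opted in to clipping.
    if (worst < -1e-8 * max(lambda) && !allow_approx) {
      abort(sprintf(
        "Circulant embedding is not non-negative definite (min eigenvalue %g). Set `allow_approx = TRUE` to clip.",
        worst
      ))
    }
    lambda <- pmax(lambda, 0)
  }
  with_seed_or_not(seed, {
    u <- rnorm(m)
    v <- rnorm(m)
    w <- complex(length.out = m)
    half <- m / 2L
    w[1L] <- sqrt(lambda[1L]) * u[1L]
    w[half + 1L] <- sqrt(lambda[half + 1L]) * u[half + 1L]
    if (half >= 2L) {
      idx <- 2L:half
      w[idx] <- sqrt(lambda[idx] / 2) * complex(real = u[idx], imaginary = v[idx])
      w[m + 2L - idx] <- Conj(w[idx])
    }
    x <- Re(fft(w)) / sqrt(m)
    x[seq_len(n)]
  })
}

#' Simulate Gaussian white noise
#'
#' Independent, identically distributed Gaussian samples; the H = 0.5 special
#' case of fGn, and the natural null series for the analysis pipeline.
#'
#' @inheritParams fgn
#' @return A tibble with columns `time` and `value`.
#' @export
white_noise <- function(n, variance = 1, seed = NULL) {
  n <- check_count(n, "n", lower = 1L)
  check_number(variance, "variance", 0, closed_lower = FALSE)
  values <- with_seed_or_not(seed, rnorm(n, sd = sqrt(variance)))
  tibble(time = seq_len(n), value = values)
}

#' Simulate fractional Brownian motion
#'
#' The cumulative sum of an fGn draw with the same seed: a nonstationary
#' series whose DFA scaling exponent is H + 1, used to exercise the
#' alpha > 1 branch of the Hurst mapping. First differences (with the first
#' sample prepended) recover the underlying fGn exactly.
#'
#' @inheritParams fgn
#' @return A tibble with columns `time` and `value`.
#' @export
fbm <- function(n, hurst, variance = 1, seed = NULL, allow_approx = FALSE) {
  increments <- fgn(n, hurst, variance, seed, allow_approx)
  tibble(time = increments$time, value = cumsum(increments$value))
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking with soft raised-cosine edges: components inside
#' `[low_hz, high_hz]` pass, components outside are attenuated to zero over a
#' transition band, and the mean (DC) is always removed. Zero-phase by
#' construction (a real mask applied to the spectrum).
#'
#' @param ts A tibble with a `value` column (e.g. from [fgn()]) or a numeric
#'   vector.
#' @param tr Sampling interval in seconds (fMRI repetition time).
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz <= 1/(2*tr)` (Nyquist).
#' @param transition_hz Width of each raised-cosine edge in Hz (default two
#'   frequency bins).
#' @return Same shape as the input (`tibble` in, tibble out; vector in,
#'   vector out) with filtered values.
#' @examples
#' x <- white_noise(300, seed = 1)
#' y <- bandpass(x, tr = 2, low_hz = 0.01, high_hz = 0.1)
#' @export
bandpass <- function(ts, tr, low_hz = 0.01, high_hz = 0.1, transition_hz = NULL) {
  vec_in <- is.numeric(ts)
  x <- if (vec_in) ts else ts$value
  check_series(x, "ts")
  check_number(tr, "tr", 0, closed_lower = FALSE)
  nyquist <- 1 / (2 * tr)
  check_number(low_hz, "low_hz", 0, nyquist)
  check_number(high_hz, "high_hz", 0, nyquist)
  if (low_hz >= high_hz) {
    abort(sprintf(
      "Pass band is empty: low_hz (%g) must be below high_hz (%g); Nyquist for tr = %g s is %g Hz.",
      low_hz, high_hz, tr, nyquist
    ))
  }
  n <- length(x)
  freqs <- seq(0L, n - 1L)
  freqs <- pmin(freqs, n - freqs) / (n * tr) # two-sided frequency axis
  df <- 1 / (n * tr)
  w <- transition_hz %||% (2 * df)
  mask <- cosine_taper(freqs, low_hz, high_hz, w)
  mask[1L] <- 0 # DC always removed
  y <- Re(fft(fft(x - mean(x)) * mask, inverse = TRUE)) / n
  if (vec_in) y else {
    out <- ts
    out$value <- y
    out
  }
}

# Raised-cosine pass mask: 1 inside [low, high], 0 beyond a transition of
# width w on each side.
cosine_taper <- function(f, low, high, w) {
  up <- ifelse(f <= low - w, 0,
        ifelse(f >= low, 1, 0.5 * (1 + cos(pi * (low - f) / w))))
  if (low == 0) up <- rep(1, length(f))
  down <- ifelse(f >= high + w, 0,
          ifelse(f <= high, 1, 0.5 * (1 + cos(pi * (f - high) / w))))
  up * down
}
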