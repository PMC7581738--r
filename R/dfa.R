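#' Cumulative profile of a time series
#'
#' Subtracts the series mean from every sample and cumulatively sums the
#' result. This is the "integrated" signal on which the windowed detrending
#' of DFA operates; by construction the last profile value is zero up to
#' rounding.
#'
#' @param x Numeric vector (a constant series is allowed and yields an
#'   all-zero profile; non-finite values are an error).
#' @return Numeric vector of the same length.
#' @examples
#' dfa_profile(c(1, -1, 1, -1)) # 1 0 1 0
#' @export
dfa_profile <- function(x) {
  if (is.data.frame(x)) x <- x$value
  check_series(x, "x")
  cumsum(x - mean(x))
}

#' Mean detrended fluctuation at one window size
#'
#' Splits the profile into consecutive non-overlapping windows of `window`
#' samples, anchored at the start (a trailing partial window is discarded).
#' In each window a least-squares polynomial of order `detrend_order` is
#' removed and the root-mean-square of the residuals is taken as that
#' window's fluctuation. Two aggregations across windows are offered:
#' `"mean"` (the arithmetic mean of per-window RMS values) and `"rms"`
#' (the canonical root-mean-square over all windows' residual variances).
#'
#' @param profile Numeric vector, usually from [dfa_profile()].
#' @param window Window length in samples (must allow >= 1 complete window).
#' @param detrend_order Polynomial detrending order (default 1, i.e. DFA-1).
#' @param aggregation `"mean"` (default) or `"rms"`; see Details in [dfa()].
#' @return A single non-negative number F(n).
#' @examples
#' window_fluctuation(c(0, 1, 0, 1, 0, 1), 3) # sqrt(2/9)
#' @export
window_fluctuation <- function(profile, window, detrend_order = 1,
                               aggregation = c("mean", "rms")) {
  aggregation <- arg_match(aggregation)
  check_series(profile, "profile", min_len = 2L)
  # a window needs at least one residual degree of freedom beyond the fit
  window <- check_count(window, "window", lower = as.integer(detrend_order + 2))
  if (window > length(profile)) {
    abort(sprintf("Window (%d) exceeds profile length (%d): no complete window.",
                  window, length(profile)))
  }
  f <- fluctuation_matrix(matrix(profile, ncol = 1), window, detrend_order)
  if (aggregation == "mean") mean(f$rms) else sqrt(mean(f$rms^2))
}

# Residual RMS per window for every column of `profiles` (one column per
# series). Returns list(rms = matrix [n_windows x n_series]). The projection
# onto polynomial residuals is precomputed once per window size, so the whole
# computation is two matrix products however many series are passed.
fluctuation_matrix <- function(profiles, window, detrend_order) {
  len <- nrow(profiles)
  k <- len %/% window
  if (k < 1L) abort("Fewer than one complete window.")
  used <- profiles[seq_len(k * window), , drop = FALSE]
  # stack windows of every series side by side: window x (k * n_series)
  stacked <- matrix(used, nrow = window)
  X <- outer(seq_len(window), 0:detrend_order, `^`)
  resid_proj <- diag(window) - X %*% solve(crossprod(X), t(X))
  res <- resid_proj %*% stacked
  rms <- sqrt(colMeans(res^2))
  list(rms = matrix(rms, nrow = k))
}

#' Select DFA window sizes for a series length
#'
#' Filters a candidate grid to the admissible range: windows below
#' `min_window` are dropped (short windows deviate from log-log linearity on
#' band-limited BOLD signals), and windows above `floor(n * max_window_frac)`
#' are dropped (the one-tenth-of-signal-length rule). The default grid is
#' 12, 15, 20, 25, 30 samples.
#'
#' @param n_timepoints Series length in samples (volumes).
#' @param grid Candidate window sizes (strictly increasing).
#' @param min_window Smallest admissible window (default 12).
#' @param max_window_frac Largest admissible window as a fraction of the
#'   series length (default 1/10).
#' @return Integer vector of admissible window sizes.
#' @examples
#' select_windows(300) # 12 15 20 25 30
#' select_windows(120) # 12
#' @export
select_windows <- function(n_timepoints, grid = c(12L, 15L, 20L, 25L, 30L),
                           min_window = 12L, max_window_frac = 1 / 10) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 2L)
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  max_window <- floor(n_timepoints * max_window_frac)
  keep <- grid[grid >= min_window & grid <= max_window]
  if (length(keep) == 0) {
    abort(sprintf(
      paste0("No admissible window size: the maximum window is one tenth of the ",
             "signal length (floor(%d/%g) = %d), below the minimum window %d."),
      n_timepoints, 1 / max_window_frac, max_window, min_window
    ))
  }
  as.integer(keep)
}

#' Least-squares slope of the log-log fluctuation function
#'
#' Ordinary least squares of log F(n) on log n (natural logarithms; the slope
#' and R-squared are base-invariant). The goodness of fit is the squared
#' Pearson correlation of the logged points.
#'
#' @param windows Window sizes n.
#' @param fluctuations Corresponding F(n) values, all strictly positive.
#' @return A list with `alpha` (slope), `intercept`, and `r_squared`.
#' @export
fit_scaling_exponent <- function(windows, fluctuations) {
  stopifnot(length(windows) == length(fluctuations), length(windows) >= 2)
  if (any(fluctuations <= 0)) {
    abort("All fluctuations must be positive: F(n) = 0 signals a degenerate (noise-free) input.")
  }
  lx <- log(windows)
  ly <- log(fluctuations)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  r2 <- if (length(lx) == 2) 1 else cor(lx, ly)^2
  list(alpha = slope, intercept = mean(ly) - slope * mean(lx), r_squared = r2)
}

#' Map a DFA scaling exponent to a Hurst exponent and regime
#'
#' For alpha in (0, 1] the series is stationary and H = alpha, classified as
#' anticorrelated (H < 0.5), random (H = 0.5 within 1e-12), or persistent
#' (H > 0.5, long-range temporal correlations). For alpha > 1 the series is
#' nonstationary and H = alpha - 1.
#'
#' @param alpha Positive scaling exponent (log-log slope).
#' @return A list with `hurst` and `regime`.
#' @examples
#' hurst_from_alpha(0.75)
#' hurst_from_alpha(1.3)
#' @export
hurst_from_alpha <- function(alpha) {
  check_number(alpha, "alpha", 0, closed_lower = FALSE)
  if (alpha > 1) {
    list(hurst = alpha - 1, regime = "nonstationary")
  } else {
    regime <- if (abs(alpha - 0.5) <= 1e-12) "random"
      else if (alpha < 0.5) "anticorrelated"
      else "persistent"
    list(hurst = alpha, regime = regime)
  }
}

#' Spectral power-law exponent from a Hurst exponent
#'
#' For stationary fGn the power spectrum follows P(f) ~ 1/f^beta with
#' beta = 2H - 1.
#'
#' @param hurst Hurst exponent in (0, 1].
#' @return beta = 2 * hurst - 1.
#' @export
beta_from_hurst <- function(hurst) {
  check_number(hurst, "hurst", 0, 1, closed_lower = FALSE)
  2 * hurst - 1
}

#' Detrended fluctuation analysis of one time series
#'
#' Runs the full DFA pipeline: mean-subtracted cumulative profile, windowed
#' polynomial detrending at each window size, least-squares log-log fit of
#' the fluctuation function, and mapping of the slope to a Hurst exponent,
#' regime label, and spectral exponent beta.
#'
#' @details
#' The per-window fluctuation is the RMS of detrending residuals; across
#' windows the default aggregation is their arithmetic **mean**, matching the
#' "average the per-window standard deviations" convention of widely used
#' fluctuation-analysis code, rather than the canonical Peng pooled RMS.
#' Both give the same scaling exponent in expectation; `aggregation = "rms"`
#' switches to the canonical pooling for comparison. Windows are anchored at
#' the start of the profile and a trailing remainder is discarded.
#'
#' @param x Numeric vector, or a tibble with a `value` column.
#' @param windows Window sizes; `NULL` (default) applies [select_windows()]
#'   to the default 12-30 grid with the one-tenth rule.
#' @param detrend_order Polynomial detrending order (default 1: DFA-1).
#' @param aggregation `"mean"` (default) or `"rms"`.
#' @return An object of class `dfa_fit` with elements `alpha`, `hurst`,
#'   `regime`, `beta` (NA in the nonstationary regime), `r_squared`,
#'   `fluctuations` (tibble of window, fluctuation), `n`, and the settings
#'   used. [tidy()] returns the fluctuation table, [glance()] the one-row fit
#'   summary, and [autoplot()] the log-log diagnostic plot.
#' @examples
#' fit <- dfa(fgn(300, hurst = 0.8, seed = 1))
#' glance(fit)
#' @export
dfa <- function(x, windows = NULL, detrend_order = 1,
                aggregation = c("mean", "rms")) {
  aggregation <- arg_match(aggregation)
  if (is.data.frame(x)) x <- x$value
  check_series(x, "x")
  if (sd(x) == 0) {
    abort("Constant series: zero fluctuation at every window, DFA is undefined.")
  }
  windows <- windows %||% select_windows(length(x))
  windows <- vapply(windows, check_count, integer(1), name = "windows")
  prof <- dfa_profile(x)
  f <- map_dbl(windows, function(w) {
    window_fluctuation(prof, w, detrend_order, aggregation)
  })
  fit <- fit_scaling_exponent(windows, f)
  hr <- hurst_from_alpha(fit$alpha)
  structure(
    list(
      alpha = fit$alpha, hurst = hr$hurst, regime = hr$regime,
      beta = if (hr$regime == "nonstationary") NA_real_ else beta_from_hurst(hr$hurst),
      r_squared = fit$r_squared, intercept = fit$intercept,
      fluctuations = tibble(window = windows, fluctuation = f),
      n = length(x), detrend_order = detrend_order, aggregation = aggregation
    ),
    class = "dfa_fit"
  )
}

# Vectorised DFA over the columns of a matrix of series (shared length and
# window grid). Used by the pipeline and simulation helpers; returns one row
# per series. Identical arithmetic to dfa(), minus per-series bookkeeping.
dfa_matrix <- function(mat, windows = NULL, detrend_order = 1,
                       aggregation = "mean") {
  n <- nrow(mat)
  windows <- windows %||% select_windows(n)
  profiles <- apply(mat, 2, function(col) cumsum(col - mean(col)))
  logf <- vapply(windows, function(w) {
    per_win <- fluctuation_matrix(profiles, w, detrend_order)$rms
    f <- if (aggregation == "mean") colMeans(per_win) else sqrt(colMeans(per_win^2))
    log(f)
  }, numeric(ncol(mat)))
  logf <- matrix(logf, nrow = ncol(mat)) # series x windows
  lx <- log(windows)
  cx <- lx - mean(lx)
  cy <- logf - rowMeans(logf)
  alpha <- as.vector(cy %*% cx) / sum(cx^2)
  r2 <- as.vector(cy %*% cx)^2 / (rowSums(cy^2) * sum(cx^2))
  tibble(
    alpha = alpha,
    hurst = ifelse(alpha > 1, alpha - 1, alpha),
    regime = dplyr::case_when(
      alpha > 1 ~ "nonstationary",
      abs(alpha - 0.5) <= 1e-12 ~ "random",
      alpha < 0.5 ~ "anticorrelated",
      .default = "persistent"
    ),
    r_squared = if (length(windows) == 2) rep(1, length(alpha)) else r2
  )
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf(
    "<dfa_fit> n = %d, windows %s (DFA-%d, %s aggregation)\n  alpha = %.4f, H = %.4f (%s), R^2 = %.4f\n",
    x$n, paste(x$fluctuations$window, collapse = "/"), x$detrend_order,
    x$aggregation, x$alpha, x$hurst, x$regime, x$r_squared
  ))
  invisible(x)
}

#' @rdname dfa
#' @param x,object A `dfa_fit`.
#' @param ... Unused.
#' @export
tidy.dfa_fit <- function(x, ...) {
  mutate(x$fluctuations,
         fitted = exp(x$intercept) * .data$window^x$alpha)
}

#' @rdname dfa
#' @export
glance.dfa_fit <- function(x, ...) {
  tibble(
    alpha = x$alpha, hurst = x$hurst, regime = x$regime, beta = x$beta,
    r_squared = x$r_squared, n = x$n, n_windows = nrow(x$fluctuations)
  )
}

#' @rdname dfa
#' @export
autoplot.dfa_fit <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$window, y = .data$fluctuation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "window size n (samples)", y = "F(n)",
      title = sprintf("DFA: alpha = %.3f, H = %.3f (%s), R² = %.3f",
                      object$alpha, object$hurst, object$regime, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
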