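# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's vectorised code paths.

# Textbook DFA: profile, per-window polynomial fit via lm(), RMS residuals,
# arithmetic-mean aggregation, slope via closed-form OLS on logged points.
naive_dfa_alpha <- function(x, windows, detrend_order = 1) {
  prof <- cumsum(x - mean(x))
  f <- vapply(windows, function(w) {
    k <- floor(length(prof) / w)
    rms <- vapply(seq_len(k), function(j) {
      seg <- prof[((j - 1) * w + 1):(j * w)]
      t <- seq_len(w)
      res <- stats::residuals(stats::lm(seg ~ poly(t, detrend_order, raw = TRUE)))
      sqrt(mean(res^2))
    }, numeric(1))
    mean(rms)
  }, numeric(1))
  lx <- log(windows); ly <- log(f)
  fit <- stats::lm(ly ~ lx)
  list(alpha = unname(coef(fit)[2]), r_squared = stats::cor(lx, ly)^2, f = f)
}

# fGn by direct Cholesky factorisation of the full covariance matrix.
cholesky_fgn <- function(n, hurst, seed) {
  g <- fgn_autocovariance(0:(n - 1), hurst)
  sigma <- stats::toeplitz(g)
  L <- t(chol(sigma))
  withr::with_seed(seed, as.vector(L %*% rnorm(n)))
}

# Paired data with a prescribed smaller signed-rank sum: differences are the
# ranks 1..n with the listed ranks made negative.
signed_rank_pairs <- function(n, negative_ranks) {
  d <- seq_len(n)
  d[negative_ranks] <- -d[negative_ranks]
  list(x = d, y = rep(0, n))
}

# A complete synthetic recordings tibble without going through fgn(), for
# pipeline structure tests (white-noise series).
toy_recordings <- function(n_subjects = 4, n_rois = 3, n_timepoints = 60,
                           sessions = c("RS1", "FE", "RS2"), seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      subject = sprintf("sub%02d", seq_len(n_subjects)),
      session = sessions, roi = sprintf("ROI%03d", seq_len(n_rois)),
      stringsAsFactors = FALSE
    )
    tibble::tibble(
      subject = grid$subject, session = grid$session, roi = grid$roi, tr = 2,
      series = lapply(seq_len(nrow(grid)), function(i) rnorm(n_timepoints))
    )
  })
}
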