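test_that("the cumulative profile matches hand computations and telescopes to zero", {
  expect_equal(dfa_profile(c(3, 3, 3, 3)), c(0, 0, 0, 0))
  expect_equal(dfa_profile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  x <- white_noise(500, seed = 2)$value
  prof <- dfa_profile(x)
  expect_lt(abs(prof[length(prof)]), 1e-9 * length(x) * max(abs(x)))
  expect_error(dfa_profile(c(1, NA, 3)), "non-finite")
})

test_that("window fluctuation matches hand least-squares computations", {
  # exactly linear profile: DFA-1 removes it entirely
  expect_equal(window_fluctuation(2.5 * (1:20) - 3, window = 5), 0)
  # [0,1,0,1,0,1], window 3: residuals (-1/3, 2/3, -1/3) in both windows
  expect_equal(window_fluctuation(c(0, 1, 0, 1, 0, 1), 3), sqrt(2 / 9), tolerance = 1e-12)
  # trailing partial window is discarded: length 6, window 4 uses only [1..4]
  prof <- c(0.3, -1.2, 0.5, 2.0, 99, -99)
  expect_equal(window_fluctuation(prof, 4), window_fluctuation(prof[1:4], 4))
  expect_error(window_fluctuation(c(1, 2, 3), 5), "complete window")
})

test_that("window selection applies the minimum and one-tenth rules", {
  expect_equal(select_windows(300), c(12L, 15L, 20L, 25L, 30L))
  expect_equal(select_windows(120), 12L)
  expect_error(select_windows(119), "one tenth")
  expect_equal(select_windows(250), c(12L, 15L, 20L, 25L))
})

test_that("the log-log fit recovers exact power laws and matches lm()", {
  w <- c(12, 15, 20, 25, 30)
  fit <- fit_scaling_exponent(w, 3 * w^0.5)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit_scaling_exponent(c(10, 20), c(1, 3))$r_squared, 1)
  expect_error(fit_scaling_exponent(w, c(0, 1, 2, 3, 4)), "positive")

  f <- exp(withr::with_seed(3, rnorm(5, mean = 1)))
  fit2 <- fit_scaling_exponent(w, f)
  ref <- stats::lm(log(f) ~ log(w))
  expect_equal(fit2$alpha, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit2$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("alpha maps to Hurst exponent and regime by the stationarity branch", {
  expect_equal(hurst_from_alpha(0.5), list(hurst = 0.5, regime = "random"))
  expect_equal(hurst_from_alpha(1.2), list(hurst = 1.2 - 1, regime = "nonstationary"))
  expect_equal(hurst_from_alpha(0.75), list(hurst = 0.75, regime = "persistent"))
  expect_equal(hurst_from_alpha(0.3)$regime, "anticorrelated")
  expect_equal(hurst_from_alpha(1)$regime, "persistent")
  expect_error(hurst_from_alpha(0), "alpha")
  expect_equal(beta_from_hurst(0.5), 0)
  expect_equal(beta_from_hurst(1), 1)
  expect_equal(beta_from_hurst(0.75), 0.5)
})

test_that("dfa() agrees with an independent textbook implementation", {
  x <- white_noise(300, seed = 13)$value
  fit <- dfa(x)
  oracle <- naive_dfa_alpha(x, c(12, 15, 20, 25, 30))
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-9)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-9)
  expect_equal(fit$fluctuations$fluctuation, oracle$f, tolerance = 1e-9)
  expect_true(fit$regime %in% c("random", "anticorrelated", "persistent"))
  expect_lt(abs(fit$alpha - 0.5), 0.15)
})

test_that("dfa() recovers long-series fGn and flags nonstationary fBm", {
  long <- fgn(4096, hurst = 0.8, seed = 6)$value
  fit <- dfa(long, windows = c(12, 15, 20, 25, 30, 50, 100, 200, 400))
  expect_lt(abs(fit$hurst - 0.8), 0.05)
  expect_equal(fit$beta, 2 * fit$hurst - 1)

  bm <- fbm(1000, hurst = 0.3, seed = 6)$value
  bfit <- dfa(bm, windows = c(12, 15, 20, 25, 30, 50, 100))
  expect_equal(bfit$regime, "nonstationary")
  expect_lt(abs(bfit$hurst - 0.3), 0.15)
  expect_true(is.na(bfit$beta))

  expect_error(dfa(rep(1, 300)), "Constant")
})

test_that("alpha and R-squared are invariant under affine transforms of the input", {
  x <- fgn(300, 0.7, seed = 17)$value
  base <- dfa(x)
  for (a in c(-3, 0.2, 10)) {
    for (b in c(-5, 0, 2)) {
      fit <- dfa(a * x + b)
      expect_equal(fit$alpha, base$alpha, tolerance = 1e-9)
      expect_equal(fit$r_squared, base$r_squared, tolerance = 1e-9)
    }
  }
})

test_that("mean F(n) is non-negative and non-decreasing for white noise", {
  f <- vapply(1:100, function(i) {
    dfa(white_noise(300, seed = 300 + i)$value)$fluctuations$fluctuation
  }, numeric(5))
  mean_f <- rowMeans(f)
  expect_true(all(mean_f >= 0))
  expect_true(all(diff(mean_f) > 0))
})

test_that("integrating a series shifts alpha by about one", {
  x <- fgn(4096, 0.6, seed = 23)$value
  w <- c(12, 15, 20, 25, 30, 50, 100)
  a_x <- dfa(x, windows = w)$alpha
  a_int <- dfa(cumsum(x), windows = w)$alpha
  expect_lt(abs(a_int - (a_x + 1)), 0.1)
})

test_that("short-series Hurst recovery is nearly unbiased with controlled spread", {
  # estimator for known-stationary input is the raw slope alpha
  for (h in c(0.6, 0.7, 0.8)) {
    alphas <- fractalrest:::dfa_matrix(
      vapply(1:200, function(i) fgn(300, h, seed = round(h * 1e4) + i)$value,
             numeric(300))
    )$alpha
    expect_lt(abs(mean(alphas) - h), 0.05)
    expect_lt(sd(alphas), 0.12)
  }
})

test_that("log-log fits on short fGn are tight (R-squared above 0.95 on average)", {
  r2 <- fractalrest:::dfa_matrix(
    vapply(1:100, function(i) fgn(300, 0.75, seed = 5000 + i)$value, numeric(300))
  )$r_squared
  expect_gt(mean(r2), 0.95)
})

test_that("the batch backend, tidiers, and aggregation modes are consistent", {
  X <- vapply(1:5, function(i) fgn(300, 0.7, seed = 40 + i)$value, numeric(300))
  batch <- fractalrest:::dfa_matrix(X)
  for (j in 1:5) {
    single <- dfa(X[, j])
    expect_equal(batch$alpha[j], single$alpha, tolerance = 1e-12)
    expect_equal(batch$r_squared[j], single$r_squared, tolerance = 1e-12)
  }
  fit <- dfa(X[, 1])
  expect_named(glance(fit),
               c("alpha", "hurst", "regime", "beta", "r_squared", "n", "n_windows"))
  expect_equal(nrow(tidy(fit)), 5)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  # canonical pooled-RMS aggregation gives a close but distinct estimate
  alt <- dfa(X[, 1], aggregation = "rms")
  expect_false(identical(alt$alpha, fit$alpha))
  expect_lt(abs(alt$alpha - fit$alpha), 0.1)
})
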