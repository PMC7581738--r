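test_that("signal variance uses the population divisor by default", {
  expect_equal(signal_variance(rep(7, 10)), 0)
  expect_equal(signal_variance(c(1, 2, 3)), 2 / 3)
  expect_equal(signal_variance(c(1, 2, 3), ddof = 1), 1)
  # Monte-Carlo: single draws within 25%, replicate mean within 5%
  v <- vapply(1:100, function(i) signal_variance(fgn(300, 0.7, 400, seed = i)$value),
              numeric(1))
  expect_lt(abs(mean(v) - 400) / 400, 0.05)
})

test_that("the signed-rank convention reproduces printed n = 23 statistics", {
  # smaller rank sum 62 (negative ranks 17, 22, 23)
  p62 <- signed_rank_pairs(23, c(17, 22, 23))
  res <- wilcoxon_signed_rank(p62$x, p62$y)
  expect_equal(res$w, 62)
  expect_equal(sprintf("%.4f", res$p_value), "0.0208")
  expect_equal(res$z, (62 - 138) / sqrt(23 * 24 * 47 / 24), tolerance = 1e-12)

  # W at the null mean 138: p prints as 1.0000
  p138 <- signed_rank_pairs(23, c(15, 18, 19, 20, 21, 22, 23))
  res2 <- wilcoxon_signed_rank(p138$x, p138$y)
  expect_equal(res2$w, 138)
  expect_equal(sprintf("%.4f", res2$p_value), "1.0000")
})

test_that("signed-rank identities and invariances hold", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(6:30, 1)
      x <- rnorm(n); y <- rnorm(n)
      d <- x - y
      r <- rank(abs(d))
      expect_equal(sum(r[d > 0]) + sum(r[d < 0]), n * (n + 1) / 2)
      expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                   wilcoxon_signed_rank(y, x)$p_value, tolerance = 1e-12)
      # matches the standard implementation without continuity correction
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
      )
      expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  # p decreases as W moves away from the null mean (W = 23, 45, 62, 73 here)
  ps <- vapply(list(c(23), c(22, 23), c(17, 22, 23), c(12, 16, 22, 23)), function(neg) {
    pr <- signed_rank_pairs(23, neg)
    wilcoxon_signed_rank(pr$x, pr$y)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("zeros are dropped, degenerate input yields p = 1, mismatch errors", {
  res <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, -4, 5, 6), rep(0, 8))
  expect_equal(res$n_pairs, 6L)
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
  expect_true(is.na(wilcoxon_signed_rank(1:5, 1:5)$w))
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "equal length")
})

test_that("exact enumeration at n = 5 matches the full sign-assignment distribution", {
  x <- c(1.2, -0.7, 2.3, 0.4, -1.9)
  y <- rep(0, 5)
  exact <- wilcoxon_signed_rank(x, y, exact = TRUE)
  # brute force over all 2^5 sign assignments of ranks of |d|
  r <- rank(abs(x))
  wplus <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 5)), 1,
                 function(s) sum(r[s]))
  obs <- wilcoxon_signed_rank(x, y)$w
  mu <- 5 * 6 / 4
  p_brute <- mean(abs(wplus - mu) >= abs(obs - mu))
  expect_equal(exact$p_value, p_brute, tolerance = 1e-12)
  expect_equal(exact$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # the documented approximation gap: normal approximation differs at n = 5
  approx <- wilcoxon_signed_rank(x, y)
  expect_lt(abs(approx$p_value - exact$p_value), 0.2)
})

test_that("Benjamini-Hochberg adjustment is correct, monotone, and idempotent", {
  expect_equal(bh_fdr(0.03), 0.03) # m = 1: q = p
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4)) # hand step-up
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  # idempotent on a flat q family (as produced by the hand example above);
  # for general families reapplication can only move q upward
  expect_equal(bh_fdr(rep(0.04, 4)), rep(0.04, 4))
  p <- withr::with_seed(11, runif(50))
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p
  expect_true(all(bh_fdr(q) >= q - 1e-12))
  # step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
  ord <- order(p)
  m <- length(p)
  q_oracle <- rev(cummin(rev(pmin(1, sort(p) * m / seq_len(m)))))[rank(p, ties.method = "first")]
  expect_equal(q, q_oracle, tolerance = 1e-12)
})

test_that("Spearman correlation matches a rank/Pearson oracle and is monotone-invariant", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)

  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 3, 7, 6, 6)
  res <- spearman(x, y)
  expect_equal(res$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  tstat <- res$rho * sqrt((8 - 2) / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), 8 - 2), tolerance = 1e-10)

  z <- withr::with_seed(2, rnorm(20))
  w <- withr::with_seed(3, rnorm(20))
  expect_equal(spearman(exp(z), w)$rho, spearman(z, w)$rho, tolerance = 1e-12)
  expect_error(spearman(rep(1, 10), 1:10), "Constant")
})

test_that("the fit-quality gate excludes on significant R-squared shifts at the nominal rate", {
  expect_true(fit_quality_gate(rep(0.97, 23), rep(0.97, 23))$include)

  shifted <- signed_rank_pairs(23, c(17, 22, 23)) # W = 62, p = 0.0208 < 0.05
  gate <- fit_quality_gate(0.9 + shifted$x / 1000, rep(0.9, 23))
  expect_false(gate$include)
  expect_equal(gate$w, 62)

  # type-I rate on equal-distribution sessions is about alpha
  rate <- mean(vapply(1:1000, function(i) {
    withr::with_seed(7000 + i, {
      a <- runif(23, 0.9, 1)
      b <- runif(23, 0.9, 1)
    })
    !fit_quality_gate(a, b)$include
  }, logical(1)))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
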