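#' Time-series variance (population convention)
#'
#' Variance with a configurable divisor; the default `ddof = 0` divides by N
#' (the population convention of common numerical libraries), so values are
#' directly comparable across series of one length.
#'
#' @param x Numeric vector or tibble with a `value` column.
#' @param ddof Delta degrees of freedom: divisor is `N - ddof` (default 0).
#' @return A single non-negative number.
#' @examples
#' signal_variance(c(1, 2, 3)) # 2/3
#' @export
signal_variance <- function(x, ddof = 0) {
  if (is.data.frame(x)) x <- x$value
  check_series(x, "x", min_len = 1L)
  ddof <- check_count(ddof, "ddof", lower = 0L)
  n <- length(x)
  if (n <= ddof) abort("Need N > ddof observations.")
  sum((x - mean(x))^2) / (n - ddof)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Two-sided paired signed-rank test with the convention set used throughout
#' this package: zero differences are dropped before ranking, ties in
#' absolute differences get average ranks, the reported statistic W is the
#' smaller of the positive- and negative-rank sums, and the p-value comes
#' from the normal approximation WITHOUT continuity correction, with
#' tie-corrected variance:
#' \deqn{z = \frac{W - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum (t^3 - t)/48}}}
#' With n = 23 pairs this convention maps W = 62 to p = 0.0208 and the null
#' mean W = 138 to p = 1.0000. An exact-enumeration mode over all 2^n sign
#' assignments is available for small n as a cross-check.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact Use exact enumeration of the signed-rank null distribution
#'   (requires no ties and n <= 25; default `FALSE`).
#' @return A one-row tibble: `w` (smaller signed-rank sum; `NA` if all
#'   differences are zero, with p = 1), `p_value`, `n_pairs` (after zero
#'   removal), `z`.
#' @examples
#' wilcoxon_signed_rank(rnorm(23), rnorm(23))
#' @export
wilcoxon_signed_rank <- function(x, y, exact = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- x - y
  if (anyNA(d)) abort("Missing values in paired differences.")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(w = NA_real_, p_value = 1, n_pairs = 0L, z = NA_real_))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (exact) {
    if (any(duplicated(r))) abort("Exact enumeration requires untied absolute differences.")
    if (n > 25) abort("Exact enumeration supported for n <= 25 only.")
    p <- wilcoxon_exact_p(w, n)
    return(tibble(w = w, p_value = p, n_pairs = n, z = NA_real_))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(tibble(w = w, p_value = 1, n_pairs = n, z = NA_real_))
  }
  z <- (w - mu) / sqrt(sigma2)
  p <- min(1, max(0, 2 * pnorm(-abs(z))))
  tibble(w = w, p_value = p, n_pairs = n, z = z)
}

# Exact two-sided p for the smaller signed-rank sum by enumerating the null
# distribution of W+ (sum over subsets of ranks 1..n), n <= 25, no ties.
wilcoxon_exact_p <- function(w, n) {
  # counts[k+1] = number of sign assignments with W+ = k
  total <- n * (n + 1) / 2
  counts <- c(1, rep(0, total))
  for (rank_i in seq_len(n)) {
    shifted <- c(rep(0, rank_i), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  mu <- total / 2
  # two-sided: P(|W+ - mu| >= |w - mu|), symmetric null
  dev <- abs(seq(0, total) - mu)
  min(1, sum(probs[dev >= abs(w - mu) - 1e-9]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values, returned in the input order. A thin, name-stable
#' wrapper over [stats::p.adjust()] so the adjustment used in every family is
#' explicit and testable in one place.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values), all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-tie ranks; two-sided p from the
#' t-approximation with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @return A one-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4) abort("Need at least 4 pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant input: ranks are undefined for a Spearman correlation.")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fit-quality gate for Hurst comparisons
#'
#' A region whose DFA goodness of fit (R-squared) differs systematically
#' between the two resting sessions cannot be compared on H, because the
#' scaling model does not describe it equally well in both; such regions are
#' excluded. The gate is a paired signed-rank test on the per-subject
#' R-squared values: exclude when p < alpha.
#'
#' @param r2_a,r2_b Per-subject R-squared vectors for the two sessions.
#' @param alpha Gate significance level (default 0.05).
#' @return A one-row tibble with `include` (logical), `w`, `p_value`,
#'   `n_pairs`.
#' @export
fit_quality_gate <- function(r2_a, r2_b, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  test <- wilcoxon_signed_rank(r2_a, r2_b)
  tibble(include = test$p_value >= alpha, w = test$w,
         p_value = test$p_value, n_pairs = test$n_pairs)
}
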