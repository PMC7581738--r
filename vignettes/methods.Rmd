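---
title: "Methods: DFA, session contrasts, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DFA, session contrasts, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalrest)
```

This vignette documents the models and conventions the package commits to,
the parameters that matter and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## The estimation target

Resting-state BOLD fluctuations show long-range temporal correlations
(LRTC): autocorrelation that decays as a power law rather than
exponentially. The package models each region's session time course as
stationary fractional Gaussian noise (fGn) with Hurst exponent $H$ and
variance $\sigma^2$, and estimates $H$ by detrended fluctuation analysis
(DFA). For fGn the autocovariance is

$$\gamma(k) = \tfrac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right),$$

$H = 0.5$ is uncorrelated noise, $H > 0.5$ persistent (LRTC), $H < 0.5$
anticorrelated, and the spectral exponent is $\beta = 2H - 1$.

## DFA conventions

`dfa()` proceeds as: (1) profile $Y_k = \sum_{i \le k}(x_i - \bar x)$;
(2) for each window size $n$, split the profile into consecutive
non-overlapping windows anchored at the start, discard the trailing
remainder, remove a least-squares polynomial of order 1 (DFA-1) per window,
and take the RMS of the residuals per window; (3) aggregate across windows;
(4) fit $\log F(n)$ on $\log n$ by ordinary least squares; the slope is
$\alpha$ and the fit quality is the squared Pearson correlation $R^2$ of
the logged points (natural logarithms; both are base-invariant).

Deliberate convention choices:

- **Aggregation.** The default aggregates per-window RMS values by their
  arithmetic *mean*, the "average the per-window standard deviations"
  convention of widely used fluctuation-analysis code, not the canonical
  pooled RMS $\sqrt{\smash{\tfrac1K\sum_k F_k^2}}$. Both are implemented
  (`aggregation = "mean"` / `"rms"`); they differ by a window-wise Jensen
  gap that is nearly constant in $\log n$, so $\alpha$ is essentially
  unchanged (the test suite bounds the difference), but $F(n)$ magnitudes
  differ.
- **Windows.** The default grid is 12, 15, 20, 25, 30 samples, filtered to
  $[\,12, \lfloor N/10 \rfloor\,]$. Twelve is the smallest window at which
  the log–log relation stays linear for band-limited BOLD-like signals;
  the $N/10$ cap keeps enough windows per size for a stable $F(n)$. With
  300 volumes the whole default grid is admissible; an empty admissible
  grid (N < 120) is an error, not a silent fallback.
- **Single-window primitive.** `window_fluctuation()` accepts any window
  with at least one residual degree of freedom (order + 2 samples); the
  stricter bound belongs to the grid defaults, and the relaxed bound keeps
  three-point hand examples computable.
- **Regimes.** $\alpha \le 1$: $H = \alpha$, classified anticorrelated /
  random / persistent with the `random` label reserved for
  $|\alpha - 0.5| \le 10^{-12}$ and $\alpha = 1$ classified persistent.
  $\alpha > 1$: nonstationary, $H = \alpha - 1$, and $\beta$ is reported as
  `NA`. The branch is a *classification* rule: when the truth is known to
  be stationary fGn (as in the recovery simulations), the estimator of
  $H$ is the raw slope $\alpha$, because estimation noise carrying
  $\hat\alpha$ across 1 would otherwise map, say, 1.01 to 0.01 and put a
  discontinuity inside the sampling distribution.
- **Degenerate inputs.** A constant series has zero fluctuation at every
  window; `dfa()` refuses it explicitly ($\log 0$ is undefined), and the
  pipeline downgrades such series to a flagged exclusion rather than an
  error, so one dead region does not abort a study.
- Affine invariance ($\alpha$, $R^2$ unchanged under $a x + b$, $a \neq 0$)
  is asserted to $10^{-9}$ in the tests; it also makes immaterial whether
  upstream extraction "normalizes" series by a global intensity factor.

## Statistical conventions

- **Paired signed-rank test.** Zero differences dropped (with the
  effective $n$ reported), average ranks for ties, $W$ = the smaller of
  the positive/negative rank sums, and a two-sided p-value from the normal
  approximation *without* continuity correction, with tie-corrected
  variance. This convention set is pinned by integer arithmetic: with
  $n = 23$, $W = 62$ gives $z = (62-138)/\sqrt{1081}$ and $p = 0.0208$,
  and $W = 138$ (the null mean) gives $p = 1.0000$ — the printed-table
  style of this literature. An exact-enumeration mode (`exact = TRUE`,
  $n \le 25$, no ties) exists as a cross-check; it is not the default
  precisely because it would not reproduce those printed values.
- **FDR.** Benjamini–Hochberg step-up via `stats::p.adjust`, one family
  per metric per contrast across regions. Covariate associations form one
  family per session × metric. BH q-values are monotone in p and never
  undercut p. Note that the step-up adjustment is *not* idempotent for
  general families (p = (0.01, 0.5) adjusts to (0.02, 0.5), which adjusts
  to (0.04, 0.5)); flat adjusted families such as the textbook
  (0.01, 0.02, 0.03, 0.04) → 0.04 example are fixed points, and only those
  weaker properties are asserted.
- **Variance.** Population convention ($\mathrm{ddof} = 0$) by default,
  matching the numerical routine conventions this analysis style inherits;
  configurable.
- **Fit-quality gate.** A region whose $R^2$ differs significantly between
  the two rest sessions (signed-rank p < 0.05) is excluded from $H$
  contrasts — if the scaling model does not describe both sessions equally
  well, comparing its index is not meaningful. The gate's type-I rate is
  verified at the nominal level by simulation.
- **Two-step contrasts.** Step 1 tests every region on the rest–rest
  contrast; step 2 tests *only* step-1 screened regions on the task
  contrasts. Screening admits regions on raw p < α by default
  (`screen_on = "fdr"` switches to q < α): the two-step design is
  deliberately exploratory, raw-p screening mirrors how such tables are
  reported, and q-values are always emitted alongside so the reader can
  apply the stricter rule. Subjects missing any session are rejected, not
  imputed.

## The synthetic-data generator

`study_spec()` + `simulate_study()` stand in for an unavailable empirical
dataset. Defaults describe a realistic study of this design: 23 subjects ×
3 sessions (RS1, FE, RS2) × 245 regions × 300 volumes at TR = 2 s; baseline
$H$ drawn once per region from U(0.66, 0.86) and baseline variance from
U(180, 900) signal units² — ranges chosen to match the magnitudes such
studies report per region. The empirical across-region distribution of $H$
is not known in detail; the uniform choice is a stand-in and is documented
as such. Effects are injected per session as $\Delta H$ shifts and/or
variance multipliers on designated regions, and the generator refuses
designs that push $H$ outside (0, 1).

Series are *exact* fGn draws via circulant (Davies–Harte) embedding — the
autocovariance is exact at all lags, verified in the tests against the
closed form and against direct Cholesky sampling — because recovery tests
against approximate fGn would confound simulator bias with estimator bias.
A negative embedding eigenvalue (which fGn cannot produce, but pathological
inputs could) is a hard error unless clipping is explicitly enabled. One
master seed spawns per-cell substream seeds, so a subset of a study
reproduces identically. Regions are simulated independently: the analysis
is univariate per region, so cross-regional covariance would change no
reported statistic.

An optional 0.01–0.1 Hz zero-phase band-pass (soft raised-cosine edges,
default transition two frequency bins, DC always removed) mirrors
resting-state preprocessing. It is **off** by default in recovery
simulations: band-limiting a 300-sample series whitens the low-frequency
end and biases $\hat H$ upward, so calibration claims are made on unfiltered
fGn and the filter is exercised by its own spectral tests.

What the generator does not emulate: hemodynamics, spatial/voxel structure,
motion or physiological artifacts, non-Gaussianity, and cross-regional
dependence. Passing recovery tests therefore demonstrate correctness of the
estimator and pipeline under the stated model, not robustness to everything
real fMRI data contain.

## Calibration results the tests compute

Problem sizes were chosen to keep each property measurable with comfortable
Monte-Carlo margins: 200 replicates for exponent calibration and recovery,
245 series for the $R^2$ summary, 2000 region-level replicates for the
type-I rate, 100 replicates for distributional checks.

- Mean $\hat\alpha$ over 200 white-noise series (N = 300, default grid)
  is within $0.5 \pm 0.03$ (a small positive finite-size bias, ≈ +0.01,
  is expected for DFA-1 at these window counts).
- Recovery at $H \in \{0.6, 0.7, 0.8\}$, N = 300: $|\mathrm{bias}| \le
  0.05$, SD $\le 0.12$ — so single-subject, single-session $\hat H$ is
  noisy, and the pipeline's inferences correctly live at the group level.
- Mean log–log $R^2$ across 245 ROI-like fGn series exceeds 0.95.
- The per-region null contrast (23 subjects, paired signed-rank on
  $\hat\alpha$, α = 0.05) rejects at a rate inside [0.03, 0.07].

## Known limitations

- DFA-1 with five window sizes on 300 samples has irreducible estimator
  spread (SD ≈ 0.1); contrasts inherit that noise and the design
  compensates with paired, within-subject testing.
- No multifractal extension (MF-DFA, wavelet leaders) and no overlapping
  windows beyond the config flag; no voxelwise analysis.
- Mask handling assumes a shared grid: no registration or resampling is
  performed, and masks are compared by shape (and affine when present)
  only.
- The signed-rank normal approximation is inaccurate for very small
  samples (n < 10); use `exact = TRUE` there.
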