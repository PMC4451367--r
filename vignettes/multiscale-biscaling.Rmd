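---
title: "Multiscale entropy, the bi-scaling law, and entropy features for biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy, the bi-scaling law, and entropy features for biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2mse)
```

## The estimator

Multiscale entropy (MSE) couples two scale parameters.  The *block size*
$b_s$ smooths the series by non-overlapping block averages,
$x^{(b_s)}_t = (x_{tb_s-b_s+1}+\dots+x_{tb_s})/b_s$ (`coarse_grain()`),
discarding any trailing partial block.  The *phase-space scale*
$\varepsilon$ enters through the correlation entropy of the (possibly
smoothed) data,
$$K_2(\varepsilon) = \ln C^{(m)}(\varepsilon) - \ln C^{(m+1)}(\varepsilon),$$
with $C^{(m)}(\varepsilon)$ the fraction of pairs of $m$-dimensional
delay vectors $V_i=[x_i,x_{i+L},\dots,x_{i+(m-1)L}]$ whose
maximum-coordinate (Chebyshev) distance is at most $\varepsilon$.
Evaluated at a fixed finite $\varepsilon$ this is the sample entropy.

For covariance-stationary fractal noise with Hurst parameter
$H \in (0,1)$ the block variance scales as
$\mathrm{var}(X^{(b_s)}) = \sigma^2 b_s^{2H-2}$
(`variance_scaling_exponent()`), and self-similarity turns that variance
contraction into a scale shift of the entropy curve,
$K_2^{(b_s)}(b_s^{H-1}\varepsilon) = K_2(\varepsilon)$.  Combined with
the small-scale divergence $K_2(\varepsilon) \sim -\ln\varepsilon$ this
gives the bi-scaling law
$$K_2^{(b_s)}(\varepsilon) \sim (H-1)\ln b_s - \ln\varepsilon,$$
so an ordinary least-squares fit of the MSE surface column at fixed
$\varepsilon$ against $\ln b_s$ estimates $H - 1$
(`fit_bs_scaling()`, $\hat H = 1+\mathrm{slope}$), while the fit against
$\ln\varepsilon$ at fixed $b_s$ has slope $\approx -1$ for any
stationary noise (`fit_eps_scaling()`).

### Estimator conventions

Several conventions are deliberate and affect numbers, so they are
spelled out here:

* **Matched templates.**  Both correlation sums in $K_2$ are computed
  over the same $N - mL$ templates (the Richman–Moorman sample-entropy
  convention).  With Chebyshev distance and a shared template set, an
  $(m{+}1)$-dimensional match implies an $m$-dimensional match, so
  $C^{(m+1)} \le C^{(m)}$ and $K_2 \ge 0$ hold *exactly*, not just
  asymptotically.  The standalone `correlation_integral()` instead uses
  all $N-(m-1)L$ delay vectors, the plain Grassberger–Procaccia
  definition; the two agree in the large-$N$ limit.
* **Rate normalization.**  $K_2$ is divided by $L\,\delta t$ with
  $\delta t = 1$ by default, i.e. entropies are in nats per sample.
  Only this normalization makes the $-\ln\varepsilon$ slope equal to
  $-1$ independently of $m$; dividing by $m$ as well would rescale the
  slopes by $1/m$ and destroy the bi-scaling exponents.
* **Ties.**  A pair at distance exactly $\varepsilon$ counts as within
  $\varepsilon$ (Heaviside $H(0)=1$).
* **Scale units.**  `entropy_curve()` takes $\varepsilon$ as a fraction
  of the series' standard deviation by default (the sample-entropy
  "tolerance $r$" convention).  `mse_surface()` holds the grid fixed in
  units of the **original** series across all block sizes.  This is
  essential: the $(H-1)\ln b_s$ term exists only because the smoothed
  variance shrinks under a fixed absolute scale.  Re-normalizing
  $\varepsilon$ per block size would silently remove the effect being
  measured.
* **Resolvability.**  A scale where either correlation sum has fewer
  than `min_pairs` (default 10) matching pairs is reported as undefined
  (`NA`), never as zero.  The smallest defined grid scale is
  $\varepsilon^*$ (`epsilon_star()`).  Ten pairs is small enough to
  probe deep scales on a few thousand samples yet large enough that
  $\ln C$ is not dominated by a single pair.
* **No Theiler window by default.**  Temporally adjacent pairs are kept
  (a `theiler` argument exists for strongly oversampled deterministic
  signals).
* **Delay.**  $L = 1$ throughout; the $m = 2$ and $m = 5$ settings used
  here are standard unit-delay sample-entropy configurations.

## Synthetic generators

`simulate_fgn()` uses Davies–Harte circulant embedding of the exact fGn
autocovariance
$r(k) = \tfrac{\sigma^2}{2}(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$,
which is exact in distribution at every lag — an approximate spectral
synthesis would bias precisely the long-lag correlations that the
bi-scaling fits measure.  The embedding eigenvalues are checked and the
function fails loudly (naming $H$ and $n$) if positive definiteness is
lost to rounding.  `simulate_one_over_f()` covers the $\alpha = 1$
($H = 1$) case outside the fGn family by random-phase spectral synthesis:
deterministic amplitudes $\propto f^{-\alpha/2}$, uniform phases,
Hermitian symmetry, a zeroed DC bin (exact zero mean), and unit-variance
rescaling.  `random_walk()`/`difference()` convert between increment and
integrated processes; no leading zero is prepended, so
`difference(random_walk(x))` reproduces `x` from its second sample on.

All randomness flows through a per-call `seed`; generators are
bit-reproducible and restore the caller's RNG state.

What the generators *do not* emulate about real recordings:
nonstationary trends and artifacts, multifractality, heavy-tailed or
quantized amplitudes, and ectopic beats.  Passing tests on these
generators therefore validates the estimator chain (simulation →
coarse-graining → correlation sums → regressions), not clinical
performance.  The test suite's RR-interval analog adds one realistic
ingredient — clock quantization of intervals derived from sampled ECG —
because that is the kind of measurement floor that $\varepsilon^*$
responds to.

## Shannon–Kolmogorov entropy

For a stationary Gaussian process with spectral density $\Phi(\omega)$,
the rate-distortion (Shannon–Kolmogorov) entropy at mean-square
distortion $\varepsilon^2$ follows from Kolmogorov's water-filling
formulas: find the level $\theta$ with
$\varepsilon^2 = \frac{1}{2\pi}\int_{-\pi}^{\pi}\min[\theta, \Phi]\,d\omega$,
then
$h_{SK} = \frac{1}{4\pi}\int_{-\pi}^{\pi}\max\{0,\ln(\Phi/\theta)\}\,d\omega$.
The fGn density is the power law $\Phi(\omega) = B(H)|\omega|^{1-2H}$
with $B(H) = \sigma^2(2-2H)\pi^{2H-1}$ fixed by requiring every $H$ to
share the variance $\sigma^2$; this normalization reproduces the closed
form $h_{SK}(\varepsilon) = A(H) - \ln\varepsilon$ with
$A(H) = \tfrac12\ln\sigma^2 + \tfrac12[\ln(2-2H) - (1-2H)]$
(`sk_prefactor()`), maximal at $H = 1/2$.

Numerical choices: for power-law densities both integrals are evaluated
in closed form (the $\omega \to 0$ singularity for $H > 1/2$ is
integrable and handled analytically; generic densities fall back to
adaptive quadrature), and $\theta$ is found by bisection to relative
tolerance $10^{-12}$ — the distortion residual at the solution is below
$10^{-8}$.  For a flat density $\theta = \varepsilon^2$ exactly and
$h_{SK} = \tfrac12\ln(\sigma^2/\varepsilon^2)$.

**Validity range of the closed form.**  The derivation of
$A(H) - \ln\varepsilon$ assumes the water level sits below the density
everywhere ($\theta \le \Phi$).  For $H < 1/2$ the density vanishes at
$\omega = 0$, so the assumption can only hold approximately, with an
error that grows with $\varepsilon$ and with $|H - 1/2|$: the exact
water-filling value and the closed form agree within $10^{-3}$ nats for
$\varepsilon \le 0.1\sigma$ across $H \in [0.1, 0.9]$, while at
$\varepsilon = 0.2\sigma$ and $H = 0.1$ the gap is about
$1.5\times10^{-3}$ nats.  The package therefore quotes the closed form
for $\varepsilon \le 0.1\sigma$ and always exposes both values
(`sk_entropy()` vs `sk_entropy_closed_form()`).

## Physiological features

`hrv_features()` mirrors the heart-rate-variability workflow: truncate
to the first 30000 RR intervals (configurable), analyze the *increment*
series (HRV is nonstationary with 1/f structure; its increments are the
stationary object), compute the $K_2(\varepsilon)$ curve at $m = 5$ on a
logarithmic grid reaching down to $0.01$ SD, and report
$\varepsilon^*$ plus the 6-point linear-fit error starting at
$\varepsilon^*$.  The fit error is defined as the RMS residual of the
OLS line divided by the mean $|K_2|$ over the window, in percent — a
"percentage of error" needs a reference magnitude and this one is
configurable in `fit_error_feature()` only through the window, not the
formula, to keep records comparable.

`eeg_features()` mirrors the seizure-detection workflow: difference the
record by default (EEG behaves like a random-walk process; the scaling
theory applies to increments), then report
$K_2^{(b_s)}(\varepsilon)$ at the requested cells — defaults
$b_s \in \{2, 15\}$, $\varepsilon \in \{0.2, 0.05\}$ SD of the
preprocessed record — plus a Hurst estimate over $b_s = 1..10$.  With
~4097-point records, block sizes near 20 leave only ~200 samples, so a
warning (not an error) is raised when the smoothed series drops below
250 samples.

`group_summary()` reports per-group means/SDs and a *complete
separation* flag per feature: whether the observed group ranges are
pairwise disjoint.  This is a deliberate threshold-free criterion — the
discrimination claims being mirrored are about scatter separation, not a
trained classifier — and no significance test is attached (the original
analyses mention one without naming it; adding an arbitrary choice here
would suggest false precision).

## Fitting defaults

* $\varepsilon$-scaling fits use every defined grid point unless a range
  is given; the acceptance analyses use a log grid of 16 points on
  $[0.05, 0.5]$ SD, inside the small-scale region where
  $-\ln\varepsilon$ scaling holds before the curve bends near
  $1\,$SD.
* Block-size fits default to $b_s = 1..10$; with $2^{14}$-point
  simulations that keeps at least ~1600 samples per smoothed series.
  Both ends are configurable.
* All fits are ordinary least squares; undefined scales are dropped (the
  block-size fit aborts, naming the failing $b_s$, if fewer than three
  remain).

## Problem sizes

Simulated analyses in the tests and the acceptance script use
$2^{14}$-point fGn/1/f series with $m = 2$ (a few seconds per surface
with the compiled pair-counting kernel), $2^{11}$–$2^{13}$ points for
property-style checks, and $\le 200$ points wherever results are
compared against the naive $O(N^2)$ double-loop oracles, which is
exact-equality territory.  Feature-pipeline tests use 2049–4097-point
records (the typical EEG segment length) and 3000-point RR analogs.

## Limitations

* $K_2$ needs roughly $\varepsilon^{-(m+1)}$ effective samples at the
  smallest scale; short records push $\varepsilon^*$ up and make
  small-$\varepsilon$ slopes unreliable.  The undefined-scale flagging
  makes this visible rather than silently biasing fits.
* The bi-scaling Hurst estimator assumes a mono-fractal stationary
  increment process; multifractal or strongly nonstationary data violate
  the premise (difference first, as the feature pipelines do).
* The $O(N^2)$ pair count is the exact estimator; for $N \gg 10^5$ a
  tree- or sort-based approximation would be needed, which this package
  does not implement.
* Real-recording demos (PhysioNet HRV, Bonn EEG) are not bundled; the
  feature pipelines accept any single-column text input via
  `read_series()`.
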