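# k2mse

Multiscale entropy (MSE) analysis of fractal time series, built on the
correlation entropy K2(ε), with the bi-scaling law that links MSE to the
Hurst parameter, the Shannon–Kolmogorov (rate-distortion) entropy of
fractional Gaussian noise, and entropy-based discrimination features for
physiological recordings (heart-rate variability, EEG).

## The problem and the model

MSE is one of the most widely used complexity measures for biosignals: one
coarse-grains a series over non-overlapping blocks of size *b*<sub>s</sub>,

&nbsp;&nbsp;&nbsp;&nbsp;x<sub>t</sub><sup>(b<sub>s</sub>)</sup> = (x<sub>tb<sub>s</sub>−b<sub>s</sub>+1</sub> + … + x<sub>tb<sub>s</sub></sub>) / b<sub>s</sub>,

and computes the sample entropy of the smoothed data at a phase-space
scale ε.  Sample entropy is the correlation entropy

&nbsp;&nbsp;&nbsp;&nbsp;K<sub>2</sub>(ε) = ln C<sup>(m)</sup>(ε) − ln C<sup>(m+1)</sup>(ε),

where C<sup>(m)</sup>(ε) is the fraction of pairs of m-dimensional delay
vectors within (Chebyshev) distance ε.  For fractal 1/f-type noise with
Hurst parameter H — fractional Gaussian noise (fGn) being the canonical
model — block-averaging shrinks the variance as
var(X<sup>(b<sub>s</sub>)</sup>) = σ²b<sub>s</sub><sup>2H−2</sup>, and
self-similarity then forces a **bi-scaling law**:

&nbsp;&nbsp;&nbsp;&nbsp;K<sub>2</sub><sup>(b<sub>s</sub>)</sup>(ε) ~ (H − 1) ln b<sub>s</sub> − ln ε.

Both scale parameters matter: the slope in ln ε is −1 for any stationary
noise, while the slope in ln b<sub>s</sub> (at fixed ε) is H − 1, which
makes MSE a Hurst estimator (Ĥ = 1 + slope).  White noise decays as
−½ ln b<sub>s</sub>; a 1/f process (H = 1) is flat in b<sub>s</sub>.
The package also evaluates the Shannon–Kolmogorov entropy of a stationary
Gaussian process by the Kolmogorov water-filling formula and its fGn
closed form h<sub>SK</sub>(ε) = A(H) − ln ε, which explains the −ln ε
scaling and why ε alone barely distinguishes different H.

For physiological work the package extracts the features that *do*
discriminate: the smallest resolvable scale ε\* (a pair-count noise
floor), the linear-fit error of K2(ε) vs ln ε over six scales above ε\*,
and K2 at selected (b<sub>s</sub>, ε) grid points for differenced records.

## Worked example

```r
library(k2mse)

x <- simulate_fgn(hurst = 0.7, n = 2^14, seed = 1)   # exact circulant embedding

# scaling in epsilon: slope close to -1
curve <- entropy_curve(x, eps = default_eps_grid(0.05, 0.5, 16), m = 2)
fit_eps_scaling(curve)
#> <scaling_fit> slope = -0.9846, intercept = 0.5429, fit error = 0.237%, 16 points

# scaling in block size at eps = 20% of the original SD: recovers H
surf <- mse_surface(x, block_sizes = 1:10, eps = 0.2, m = 2)
fit_bs_scaling(surf, eps = 0.2)
#> <hurst_estimate> h_hat = 0.7090 (slope -0.2910 +/- 0.0070) at eps = 0.2, bs in [1, 10]

# rate-distortion entropy of fGn: water-filling vs closed form
sk_entropy(fgn_psd(0.7), eps = 0.05)
#> <sk_result> eps = 0.05, theta = 0.0025, h_sk = 2.940319 nats/sample
sk_entropy_closed_form(0.7, eps = 0.05)
#> [1] 2.940319

# independent check through the block-variance route
variance_scaling_exponent(x)
#> <variance_scaling> slope = -0.6151 (2H-2), h_hat = 0.6925, bs in [1, 20]
```

The ε-slope magnitude near 1 confirms the −ln ε divergence; the
block-size fit recovers the simulated H = 0.7 to two decimals; and the
numeric water-filling entropy coincides with A(H) − ln ε at small ε.

A thin command-line wrapper with subcommands `simulate`, `mse`,
`biscale`, `sk` and `features` lives at `inst/cli/k2mse.R`:

```sh
Rscript inst/cli/k2mse.R simulate --kind fgn --hurst 0.7 --n 16384 --seed 1 --out x.txt
Rscript inst/cli/k2mse.R biscale --input x.txt --m 2 --eps-sd-frac 0.2 --bs 1:10
```

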