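#' Autocovariance of fractional Gaussian noise
#'
#' Closed-form autocovariance of fGn with Hurst parameter `hurst` and
#' variance `sigma2`:
#' \deqn{r(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#' For `H = 1/2` this is zero at all non-zero lags (white noise); for
#' `H > 1/2` it decays like \eqn{k^{2H-2}} (long-range correlation).
#'
#' @param hurst Hurst parameter in (0, 1).
#' @param lags Integer vector of lags (>= 0).
#' @param sigma2 Process variance.
#' @return Numeric vector of autocovariances at `lags`.
#' @examples
#' fgn_acvf(0.3, 0:3)
#' @export
fgn_acvf <- function(hurst, lags, sigma2 = 1) {
  check_hurst(hurst)
  lags <- as.numeric(lags)
  if (any(lags < 0)) stop("lags must be non-negative", call. = FALSE)
  h2 <- 2 * hurst
  (sigma2 / 2) * (abs(lags + 1)^h2 - 2 * abs(lags)^h2 + abs(lags - 1)^h2)
}

check_hurst <- function(hurst) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  invisible(hurst)
}

#' Simulate fractional Gaussian noise by circulant embedding
#'
#' Exact-in-distribution simulation of a stationary Gaussian sequence with
#' the fGn autocovariance (see [fgn_acvf()]), using the Davies-Harte
#' circulant-embedding construction: the target autocovariance out to lag
#' `n` is embedded in a circulant matrix of order `2n`, whose eigenvalues
#' (obtained by FFT) are all non-negative for fGn, and an fGn draw is the
#' real part of an FFT of complex Gaussian coefficients weighted by the
#' eigenvalue square roots.  The correlation structure is therefore correct
#' at every lag, not just asymptotically — which is what the bi-scaling
#' diagnostics downstream rely on.
#'
#' @param hurst Hurst parameter in (0, 1); 1/2 gives white noise, > 1/2
#'   persistent and < 1/2 anti-persistent correlations.
#' @param n Number of samples (>= 2).
#' @param sigma2 Target process variance.
#' @param seed Optional seed; fixed seed gives bit-reproducible output and
#'   the caller's RNG state is left untouched.
#' @return A [time_series] of length `n`.
#' @examples
#' x <- simulate_fgn(0.7, 1024, seed = 1)
#' var(ts_values(x))  # close to 1
#' @export
simulate_fgn <- function(hurst, n, sigma2 = 1, seed = NULL) {
  check_hurst(hurst)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)

  r <- fgn_acvf(hurst, 0:n, sigma2)
  cvec <- c(r, rev(r[2:n]))          # circulant first row, length 2n
  lam <- Re(fft(cvec))
  if (min(lam) < -1e-8 * max(lam))
    stop(sprintf(paste0("circulant embedding not positive definite for ",
                        "hurst = %g, n = %d (numerical degeneracy)"),
                 hurst, n), call. = FALSE)
  lam[lam < 0] <- 0

  m2 <- 2L * n
  vals <- with_seed(seed, {
    a0 <- rnorm(1); an <- rnorm(1)
    ar <- rnorm(n - 1L); ai <- rnorm(n - 1L)
    xi <- complex(length.out = m2)
    xi[1L] <- a0
    xi[n + 1L] <- an
    xi[2:n] <- complex(real = ar, imaginary = ai) / sqrt(2)
    xi[(n + 2L):m2] <- Conj(rev(xi[2:n]))
    Re(fft(sqrt(lam) * xi))[1:n] / sqrt(m2)
  })
  time_series(vals, dt = 1,
              label = sprintf("fGn H=%g sigma2=%g", hurst, sigma2),
              seed = seed)
}

#' Simulate Gaussian white noise
#'
#' @param n Number of samples (>= 2).
#' @param sigma2 Variance.
#' @param seed Optional seed (reproducible; caller RNG untouched).
#' @return A [time_series] of iid N(0, sigma2) samples.
#' @export
simulate_white_noise <- function(n, sigma2 = 1, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  vals <- with_seed(seed, rnorm(n, 0, sqrt(sigma2)))
  time_series(vals, dt = 1, label = sprintf("white noise sigma2=%g", sigma2),
              seed = seed)
}

#' Simulate 1/f^alpha noise by random-phase spectral synthesis
#'
#' Builds a Hermitian-symmetric spectrum with amplitudes proportional to
#' \eqn{f^{-\alpha/2}} (so the periodogram follows \eqn{1/f^\alpha}),
#' uniform random phases and a zeroed DC bin, inverse-transforms it, and
#' rescales to unit variance.  `alpha = 1` is the 1/f process (H = 1) not
#' covered by fGn; `alpha = 0` is white-noise-like.
#'
#' @param n Number of samples (>= 4).
#' @param alpha Spectral exponent in `[0, 3)`.
#' @param seed Optional seed.
#' @return A [time_series] with zero mean and unit variance.
#' @export
simulate_one_over_f <- function(n, alpha = 1, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("`n` must be an integer >= 4", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 3)
    stop("`alpha` must lie in [0, 3)", call. = FALSE)

  n2 <- n %/% 2L
  amp <- (1:n2)^(-alpha / 2)
  vals <- with_seed(seed, {
    s <- complex(length.out = n)      # s[1] is the DC bin, kept at 0
    if (n %% 2L == 0L) {
      kmax <- n2 - 1L
      ph <- runif(kmax, 0, 2 * pi)
      s[2:(kmax + 1L)] <- amp[1:kmax] * exp(1i * ph)
      s[n2 + 1L] <- amp[n2] * sample(c(-1, 1), 1L)  # Nyquist bin must be real
      s[(n2 + 2L):n] <- Conj(rev(s[2:(kmax + 1L)]))
    } else {
      ph <- runif(n2, 0, 2 * pi)
      s[2:(n2 + 1L)] <- amp * exp(1i * ph)
      s[(n2 + 2L):n] <- Conj(rev(s[2:(n2 + 1L)]))
    }
    x <- Re(fft(s, inverse = TRUE))
    x / sd(x)
  })
  time_series(vals, dt = 1, label = sprintf("1/f^%g noise", alpha), seed = seed)
}

#' First difference of a series
#'
#' Returns `y[i] = x[i+1] - x[i]`; the output is one sample shorter.
#' Differencing a random walk ([random_walk()]) recovers its increments
#' exactly, after the first point.
#'
#' @param x A `time_series` or numeric vector of length >= 2.
#' @return A [time_series] of length `length(x) - 1`.
#' @export
difference <- function(x) {
  v <- ts_values(x)
  if (length(v) < 3L)
    stop("need at least 3 samples to difference into a valid series", call. = FALSE)
  time_series(diff(v), dt = ts_dt(x),
              label = paste0("diff(", if (inherits(x, "time_series")) x$label else "", ")"))
}

#' Cumulative-sum (random-walk) transform
#'
#' Integrates an increment process: `y[t] = sum(x[1:t])`.  No leading zero
#' is prepended, so `difference(random_walk(x))` equals `x` with its first
#' sample dropped.  The walk of an fGn is (discretized) fractional Brownian
#' motion with periodogram exponent `-(2H + 1)`.
#'
#' @param x A `time_series` or numeric vector.
#' @return A [time_series] of the same length.
#' @export
random_walk <- function(x) {
  v <- ts_values(x)
  time_series(cumsum(v), dt = ts_dt(x),
              label = paste0("walk(", if (inherits(x, "time_series")) x$label else "", ")"))
}
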