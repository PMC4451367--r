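#' Power spectral densities for Shannon-Kolmogorov entropy
#'
#' A `gaussian_psd` packages a symmetric spectral density
#' \eqn{\Phi(\omega)} on \eqn{(-\pi, \pi]} normalized so that
#' \eqn{(1/2\pi)\int_{-\pi}^{\pi}\Phi(\omega)d\omega} equals the process
#' variance.  `fgn_psd()` is the power-law density of fractional Gaussian
#' noise, \eqn{\Phi(\omega) = B(H)|\omega|^{1-2H}} with
#' \eqn{B(H) = \sigma^2 (2-2H)\pi^{2H-1}} fixed by the variance
#' normalization (for `H = 1/2` it reduces to the flat density
#' \eqn{\Phi \equiv \sigma^2}).  `flat_psd()` is the white-noise density.
#' Power-law densities carry their exponent so the water-filling integrals
#' can be evaluated in closed form, including the integrable
#' \eqn{\omega \to 0} singularity when `H > 1/2`.
#'
#' @param hurst Hurst parameter in (0, 1).
#' @param sigma2 Process variance.
#' @return A `gaussian_psd` object with fields `phi` (vectorized function
#'   of \eqn{\omega}), `variance`, and for power laws `B` and `expo`
#'   (\eqn{1 - 2H}).
#' @examples
#' p <- fgn_psd(0.7)
#' p$phi(pi)
#' @export
fgn_psd <- function(hurst, sigma2 = 1) {
  check_hurst(hurst)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  B <- sigma2 * (2 - 2 * hurst) * pi^(2 * hurst - 1)
  e <- 1 - 2 * hurst
  structure(list(phi = function(w) B * abs(w)^e,
                 variance = sigma2, B = B, expo = e, hurst = hurst),
            class = "gaussian_psd")
}

#' @rdname fgn_psd
#' @export
flat_psd <- function(sigma2 = 1) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  structure(list(phi = function(w) rep(sigma2, length(w)),
                 variance = sigma2, B = sigma2, expo = 0, hurst = 0.5),
            class = "gaussian_psd")
}

#' @export
print.gaussian_psd <- function(x, ...) {
  cat(sprintf("<gaussian_psd> variance = %g%s\n", x$variance,
              if (!is.null(x$expo)) sprintf(", power law B|w|^%g (B = %g)", x$expo, x$B)
              else ""))
  invisible(x)
}

# mean-square distortion (1/pi) * integral_0^pi min(theta, Phi(w)) dw,
# closed form for power laws, quadrature otherwise
sk_distortion <- function(psd, theta) {
  if (theta <= 0) return(0)
  if (!is.null(psd$expo)) {
    B <- psd$B; e <- psd$expo
    if (e == 0) return(min(theta, B))
    wstar <- (theta / B)^(1 / e)           # Phi(wstar) = theta
    wstar <- min(max(wstar, 0), pi)
    pow_int <- function(a, b) B * (b^(e + 1) - a^(e + 1)) / (e + 1)
    if (e > 0) {                            # H < 1/2: Phi increasing from 0
      return((pow_int(0, wstar) + theta * (pi - wstar)) / pi)
    } else {                                # H > 1/2: Phi decreasing, singular at 0
      return((theta * wstar + pow_int(wstar, pi)) / pi)
    }
  }
  integrate(function(w) pmin(theta, psd$phi(w)), 0, pi,
            rel.tol = 1e-10, subdivisions = 500L)$value / pi
}

#' Water-filling level for a Gaussian process at distortion eps^2
#'
#' Solves the Kolmogorov water-filling condition
#' \deqn{\varepsilon^2 = \frac{1}{2\pi}\int_{-\pi}^{\pi}
#'   \min[\theta, \Phi(\omega)]\,d\omega}
#' for the water level \eqn{\theta} by bisection (the left side is
#' monotone increasing in \eqn{\theta}); for power-law densities the
#' distortion integral is evaluated in closed form, so the solution is
#' deterministic to relative tolerance `tol`.  For a flat density the
#' solution is \eqn{\theta = \varepsilon^2} exactly.
#'
#' @param psd A `gaussian_psd` (see [fgn_psd()]).
#' @param eps Positive distortion scale with `eps^2 <= variance`.
#' @param tol Relative bisection tolerance.
#' @return The water level theta.  When `eps^2 == variance` the level is
#'   the supremum of the density (`Inf` for an unbounded power law), the
#'   boundary of the `h_sk = 0` regime.
#' @export
water_filling_level <- function(psd, eps, tol = 1e-12) {
  stopifnot(inherits(psd, "gaussian_psd"))
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  e2 <- eps^2
  v <- psd$variance
  if (e2 > v * (1 + 1e-12))
    stop(sprintf(paste0("eps^2 = %g exceeds the process variance %g: ",
                        "distortion exceeds signal power (h_sk = 0 regime)"),
                 e2, v), call. = FALSE)
  if (abs(e2 - v) <= 1e-12 * v) {
    if (!is.null(psd$expo) && psd$expo < 0) return(Inf)   # sup Phi unbounded
    if (!is.null(psd$expo) && psd$expo == 0) return(psd$B)
    return(psd$phi(pi) * 0 + max(psd$phi(seq(1e-6, pi, length.out = 1e4))))
  }
  if (!is.null(psd$expo) && psd$expo == 0) return(e2)     # flat: theta = eps^2
  lo <- 0; hi <- e2
  while (sk_distortion(psd, hi) < e2) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (sk_distortion(psd, mid) < e2) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * hi) break
  }
  (lo + hi) / 2
}

#' Shannon-Kolmogorov (rate-distortion) entropy of a Gaussian process
#'
#' Evaluates the Kolmogorov formula
#' \deqn{h_{SK}(\varepsilon) = \frac{1}{4\pi}\int_{-\pi}^{\pi}
#'   \max\{0, \ln[\Phi(\omega)/\theta]\}\,d\omega}
#' with the water level \eqn{\theta} from [water_filling_level()], in nats
#' per sample.  For the fGn density and small \eqn{\varepsilon} this
#' approaches the closed form \eqn{A(H) - \ln\varepsilon} (see
#' [sk_prefactor()]); for the flat density it is
#' \eqn{\frac{1}{2}\ln(\sigma^2/\varepsilon^2)} exactly.
#'
#' @inheritParams water_filling_level
#' @return An `sk_result` list: `eps`, `theta`, `h_sk`.
#' @examples
#' sk_entropy(flat_psd(1), 0.1)$h_sk  # log(10)
#' @export
sk_entropy <- function(psd, eps, tol = 1e-12) {
  theta <- water_filling_level(psd, eps, tol = tol)
  if (!is.finite(theta)) {
    h <- 0
  } else if (!is.null(psd$expo)) {
    B <- psd$B; e <- psd$expo
    if (e == 0) {
      h <- if (B > theta) max(0, log(B / theta)) / 2 else 0
    } else {
      # integral of ln(B w^e / theta) over the region Phi > theta;
      # antiderivative of ln w is w ln w - w (finite at 0)
      wstar <- min(max((theta / B)^(1 / e), 0), pi)
      log_int <- function(a, b) {
        ia <- if (a == 0) 0 else a * log(a) - a
        (b * log(b) - b - ia) * e + (b - a) * (log(B) - log(theta))
      }
      h <- if (e < 0) log_int(0, wstar) / (2 * pi)       # Phi > theta near 0
           else log_int(wstar, pi) / (2 * pi)            # Phi > theta near pi
    }
  } else {
    h <- integrate(function(w) pmax(0, log(psd$phi(w) / theta)), 0, pi,
                   rel.tol = 1e-10, subdivisions = 500L)$value / (2 * pi)
  }
  structure(list(eps = eps, theta = theta, h_sk = max(h, 0)),
            class = "sk_result")
}

#' @export
print.sk_result <- function(x, ...) {
  cat(sprintf("<sk_result> eps = %g, theta = %g, h_sk = %.6f nats/sample\n",
              x$eps, x$theta, x$h_sk))
  invisible(x)
}

#' Closed-form small-scale SK entropy prefactor for fGn
#'
#' For fractional Gaussian noise at small distortion the SK entropy obeys
#' \eqn{h_{SK}(\varepsilon) = A(H) - \ln\varepsilon} with
#' \deqn{A(H) = \tfrac{1}{2}\ln\sigma^2_{H=1/2}
#'   + \tfrac{1}{2}\left[\ln(2-2H) - (1-2H)\right],}
#' where \eqn{\sigma^2_{H=1/2}} is the common variance of the fGn family.
#' `A(H)` is maximal at `H = 1/2` and varies weakly in between — the
#' analytic reason the phase-space scale alone cannot separate fGn of
#' different `H`.
#'
#' @param hurst Hurst parameter in (0, 1).
#' @param sigma2 Common process variance.
#' @return The prefactor A(H) in nats.
#' @examples
#' sk_prefactor(0.5)  # 0
#' @export
sk_prefactor <- function(hurst, sigma2 = 1) {
  check_hurst(hurst)
  0.5 * log(sigma2) + 0.5 * (log(2 - 2 * hurst) - (1 - 2 * hurst))
}

#' @rdname sk_prefactor
#' @param eps Positive distortion scale.
#' @return `sk_entropy_closed_form()`: the small-scale approximation
#'   `A(H) - log(eps)`.
#' @export
sk_entropy_closed_form <- function(hurst, eps, sigma2 = 1) {
  if (any(eps <= 0)) stop("`eps` must be positive", call. = FALSE)
  sk_prefactor(hurst, sigma2) - log(eps)
}
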