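# OLS of y on x with relative RMS fit error (% of mean |y|)
ols_line <- function(x, y) {
  if (length(x) < 2L) stop("need at least 2 points for a line fit", call. = FALSE)
  fit <- lm(y ~ x)
  res <- unname(fit$residuals)
  denom <- max(mean(abs(y)), .Machine$double.eps)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  stderr <- if (n > 2L && sxx > 0) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       fit_error_pct = 100 * sqrt(mean(res^2)) / denom,
       stderr = stderr)
}

#' Fit the K2 ~ -ln eps scaling of an entropy curve
#'
#' Ordinary least squares of the defined K2 values on \eqn{\ln\varepsilon}
#' over a scale range.  For fractal (1/f-type) noise the slope is expected
#' near -1; the relative RMS residual (in percent of the mean |K2| over the
#' window) quantifies how well the curve scales.
#'
#' @param curve An `entropy_curve` (see [entropy_curve()]).
#' @param eps_range Optional `c(lo, hi)` limits (same units as the curve's
#'   grid); default uses every defined scale.
#' @return A `scaling_fit`: `slope`, `intercept`, `fit_error_pct`,
#'   `stderr`, `x_range`, `n_points`.
#' @export
fit_eps_scaling <- function(curve, eps_range = NULL) {
  stopifnot(inherits(curve, "entropy_curve"))
  keep <- is.finite(curve$k2)
  if (!is.null(eps_range)) {
    stopifnot(length(eps_range) == 2L)
    keep <- keep & curve$eps >= min(eps_range) & curve$eps <= max(eps_range)
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 defined K2 points in the requested scale range",
         call. = FALSE)
  f <- ols_line(log(curve$eps[keep]), curve$k2[keep])
  structure(list(slope = f$slope, intercept = f$intercept,
                 fit_error_pct = f$fit_error_pct, stderr = f$stderr,
                 x_range = range(curve$eps[keep]), n_points = sum(keep)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> slope = %.4f, intercept = %.4f, fit error = %.3f%%, %d points\n",
              x$slope, x$intercept, x$fit_error_pct, x$n_points))
  invisible(x)
}

#' Hurst estimate from the block-size scaling of an MSE surface
#'
#' At a fixed phase-space scale the bi-scaling law predicts
#' \eqn{K_2^{(b_s)}(\varepsilon) \sim (H-1)\ln b_s - \ln\varepsilon}, so
#' the OLS slope of the surface column on \eqn{\ln b_s} estimates
#' \eqn{H - 1} and \eqn{\hat H = 1 + slope}.  White noise gives slope
#' -1/2; a 1/f process (H = 1) gives a flat column.
#'
#' @param surface An `mse_surface` (see [mse_surface()]).
#' @param eps Scale at which to read the surface (matched to the nearest
#'   grid column; must be within 1e-6 relative or a warning is raised).
#' @param bs_range `c(lo, hi)` block-size fit range (default 1..10).
#' @return A `hurst_estimate`: `h_hat`, `slope`, `stderr`, `eps_used`,
#'   `bs_range`, `n_points`.
#' @export
fit_bs_scaling <- function(surface, eps, bs_range = c(1, 10)) {
  stopifnot(inherits(surface, "mse_surface"), length(eps) == 1L, eps > 0)
  j <- which.min(abs(surface$eps - eps))
  if (abs(surface$eps[j] - eps) > 1e-6 * max(eps, 1))
    warning(sprintf("no grid column at eps = %g; using nearest eps = %g",
                    eps, surface$eps[j]))
  sel <- surface$block_sizes >= min(bs_range) & surface$block_sizes <= max(bs_range)
  bs <- surface$block_sizes[sel]
  k <- surface$k2[sel, j]
  ok <- is.finite(k)
  if (sum(ok) < 3L)
    stop(sprintf("K2 undefined (min_pairs not met) at block sizes %s; only %d defined",
                 paste(bs[!ok], collapse = ", "), sum(ok)), call. = FALSE)
  f <- ols_line(log(bs[ok]), k[ok])
  structure(list(h_hat = 1 + f$slope, slope = f$slope, stderr = f$stderr,
                 eps_used = surface$eps[j], bs_range = range(bs[ok]),
                 n_points = sum(ok)),
            class = "hurst_estimate")
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<hurst_estimate> h_hat = %.4f (slope %.4f +/- %.4f) at eps = %g, bs in [%d, %d]\n",
              x$h_hat, x$slope, x$stderr, x$eps_used,
              x$bs_range[1], x$bs_range[2]))
  invisible(x)
}

#' Smallest resolvable scale of an entropy curve
#'
#' The smallest grid scale at which K2 is defined, i.e. where both
#' correlation sums have at least `min_pairs` matching pairs.  Below this
#' scale the data cannot resolve the entropy — the quantity behaves like a
#' generalized noise floor and is a powerful discrimination feature for
#' heart-rate-variability recordings.
#'
#' @param curve An `entropy_curve`.
#' @return The smallest defined scale (in the curve's grid units).
#' @export
epsilon_star <- function(curve) {
  stopifnot(inherits(curve, "entropy_curve"))
  idx <- which(is.finite(curve$k2))
  if (length(idx) == 0L)
    stop("K2 undefined on the whole grid: no resolvable scale", call. = FALSE)
  curve$eps[idx[1L]]
}

#' Linear-fit error over the first scales above epsilon*
#'
#' Fits a line to K2 vs \eqn{\ln\varepsilon} through the first `n_points`
#' defined scales starting at [epsilon_star()] and returns the relative
#' RMS residual in percent.  Clean fractal scaling gives a small error;
#' curves with a knee or noise floor inside the window give a large one.
#'
#' @param curve An `entropy_curve`.
#' @param n_points Number of scales in the fit window (default 6).
#' @return Non-negative fit error in percent.
#' @export
fit_error_feature <- function(curve, n_points = 6) {
  stopifnot(inherits(curve, "entropy_curve"), n_points >= 3)
  idx <- which(is.finite(curve$k2))
  if (length(idx) < n_points)
    stop(sprintf("only %d defined scales; %d needed for the fit window",
                 length(idx), n_points), call. = FALSE)
  idx <- idx[seq_len(n_points)]
  ols_line(log(curve$eps[idx]), curve$k2[idx])$fit_error_pct
}
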