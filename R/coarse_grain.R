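#' Coarse-grain a series over non-overlapping blocks
#'
#' Replaces the series by the means of consecutive non-overlapping blocks
#' of `block_size` samples:
#' \deqn{x^{(b_s)}_t = (x_{t b_s - b_s + 1} + \cdots + x_{t b_s}) / b_s.}
#' Trailing samples that do not fill a block are dropped (the definition
#' uses full blocks only).  The smoothed series has length
#' `floor(N / block_size)` and sampling interval `dt * block_size`.
#'
#' @param x A `time_series` or numeric vector.
#' @param block_size Integer block size \eqn{b_s \ge 1}.
#' @return A `coarse_grained` object (also a [time_series]) with extra
#'   fields `block_size` and `parent_length`.
#' @examples
#' ts_values(coarse_grain(c(1, 2, 3, 4, 5), 2))  # 1.5 3.5
#' @export
coarse_grain <- function(x, block_size) {
  v <- ts_values(x)
  bs <- as.integer(block_size)
  if (is.na(bs) || bs < 1L) stop("`block_size` must be an integer >= 1", call. = FALSE)
  nb <- length(v) %/% bs
  if (nb < 2L)
    stop(sprintf("block_size = %d leaves fewer than 2 blocks for n = %d",
                 bs, length(v)), call. = FALSE)
  vals <- if (bs == 1L) v else colMeans(matrix(v[seq_len(nb * bs)], nrow = bs))
  out <- time_series(vals, dt = ts_dt(x) * bs,
                     label = sprintf("coarse bs=%d", bs))
  out$block_size <- bs
  out$parent_length <- length(v)
  class(out) <- c("coarse_grained", class(out))
  out
}

#' Variance scaling of coarse-grained series and Hurst estimate
#'
#' For a long-range correlated (fGn-like) process the variance of the
#' block-averaged series follows \eqn{var(X^{(b_s)}) = \sigma^2 b_s^{2H-2}},
#' so the least-squares slope of \eqn{\ln var} on \eqn{\ln b_s} estimates
#' \eqn{2H - 2}, and \eqn{\hat H = 1 + slope/2}.
#'
#' @param x A `time_series` or numeric vector.
#' @param block_sizes Integer vector of at least 3 block sizes, each valid
#'   for the series length.
#' @return A list of class `variance_scaling` with `slope`, `h_hat`,
#'   `block_sizes` and `variances`.
#' @examples
#' x <- simulate_white_noise(4096, seed = 1)
#' variance_scaling_exponent(x)$slope  # close to -1
#' @export
variance_scaling_exponent <- function(x, block_sizes = 1:20) {
  v <- ts_values(x)
  bs <- sort(unique(as.integer(block_sizes)))
  if (length(bs) < 3L) stop("need at least 3 block sizes", call. = FALSE)
  vars <- vapply(bs, function(b) var(ts_values(coarse_grain(v, b))), numeric(1))
  if (any(vars <= 0) || !all(is.finite(vars)))
    stop("degenerate (zero-variance) series: variance scaling undefined",
         call. = FALSE)
  fit <- lm(log(vars) ~ log(bs))
  slope <- unname(coef(fit)[2L])
  structure(list(slope = slope, h_hat = 1 + slope / 2,
                 block_sizes = bs, variances = vars),
            class = "variance_scaling")
}

#' @export
print.variance_scaling <- function(x, ...) {
  cat(sprintf("<variance_scaling> slope = %.4f (2H-2), h_hat = %.4f, bs in [%d, %d]\n",
              x$slope, x$h_hat, min(x$block_sizes), max(x$block_sizes)))
  invisible(x)
}
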