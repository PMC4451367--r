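#' Delay embedding of a time series
#'
#' Builds the delay vectors \eqn{V_i = [x_i, x_{i+L}, \ldots, x_{i+(m-1)L}]}
#' used by the correlation-integral machinery; there are
#' \eqn{N - (m-1)L} of them.
#'
#' @param x A `time_series` or numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param L Delay (>= 1).
#' @return Numeric matrix with one delay vector per row.
#' @examples
#' embed_series(c(1, 2, 3), m = 2)  # rows (1,2) and (2,3)
#' @export
embed_series <- function(x, m, L = 1) {
  v <- ts_values(x)
  m <- as.integer(m); L <- as.integer(L)
  if (is.na(m) || m < 1L || is.na(L) || L < 1L)
    stop("`m` and `L` must be integers >= 1", call. = FALSE)
  nv <- length(v) - (m - 1L) * L
  if (nv < 2L)
    stop(sprintf("series of length %d too short for m = %d, L = %d",
                 length(v), m, L), call. = FALSE)
  out <- matrix(0, nrow = nv, ncol = m)
  for (k in seq_len(m)) out[, k] <- v[(1L + (k - 1L) * L):(nv + (k - 1L) * L)]
  out
}

#' Correlation integral of delay-embedded vectors
#'
#' Fraction of unordered distinct pairs of m-dimensional delay vectors
#' whose Chebyshev (maximum-coordinate) distance is at most `eps`
#' (ties at exactly `eps` count as within).  All \eqn{N - (m-1)L} delay
#' vectors participate; self-pairs are excluded.
#'
#' @param x A `time_series` or numeric vector.
#' @param eps Positive scale, or an ascending vector of scales (absolute
#'   data units).
#' @param m Embedding dimension.
#' @param L Delay.
#' @param theiler Theiler window: pairs with index separation <= `theiler`
#'   are excluded (default 0, i.e. all distinct pairs).
#' @return Numeric vector in `[0, 1]`, one value per `eps`.
#' @examples
#' correlation_integral(c(0, 1, 0, 1), eps = 2, m = 1)  # 1: eps covers range
#' @export
correlation_integral <- function(x, eps, m = 2, L = 1, theiler = 0) {
  v <- ts_values(x)
  eps <- as.numeric(eps)
  if (any(eps <= 0)) stop("`eps` must be positive", call. = FALSE)
  ord <- order(eps)
  res <- pair_counts_single(v, as.integer(m), as.integer(L), eps[ord],
                            as.integer(theiler))
  if (res$n_pairs < 1) stop("no admissible vector pairs", call. = FALSE)
  out <- numeric(length(eps))
  out[ord] <- res$counts / res$n_pairs
  out
}

#' Correlation entropy K2 over a scale grid
#'
#' Estimates the correlation entropy (sample entropy) at each scale of an
#' ascending `eps` grid:
#' \deqn{K_2(\varepsilon) = \ln C^{(m)}(\varepsilon) - \ln C^{(m+1)}(\varepsilon),}
#' divided by `L * dt` so the value is an entropy rate (nats per sample
#' with the default `dt = 1`).  Both correlation sums use the same set of
#' \eqn{N - mL} templates and Chebyshev distance, the sample-entropy
#' convention, which guarantees \eqn{C^{(m+1)} \le C^{(m)}} and hence
#' \eqn{K_2 \ge 0}.  A scale where either sum has fewer than `min_pairs`
#' matching pairs is flagged undefined (`NA`), not reported as 0 — the
#' smallest defined scale is the smallest scale resolvable by the data
#' (see [epsilon_star()]).
#'
#' @param x A `time_series` or numeric vector.
#' @param eps Ascending positive scale grid.  Interpreted as fractions of
#'   the series' standard deviation when `eps_units = "sd"` (default), or
#'   as absolute data units when `"absolute"`.
#' @param m Embedding dimension (sample-entropy default 2).
#' @param L Delay (default 1).
#' @param min_pairs Minimum matching pairs for K2 to count as defined.
#' @param eps_units `"sd"` or `"absolute"`.
#' @param scale_sd Reference SD used when `eps_units = "sd"`; defaults to
#'   `sd(x)`.  [mse_surface()] passes the *original* series' SD here so
#'   that scales stay fixed in absolute units across block sizes.
#' @param theiler Theiler window (default 0; none).
#' @param dt Sampling interval used in the rate normalization (default 1:
#'   entropies per sample).
#' @return An `entropy_curve` object: fields `eps` (as supplied), `eps_abs`,
#'   `k2`, `pairs_m`, `pairs_m1`, `n_pairs`, `m`, `L`, `block_size`,
#'   `eps_units`, `min_pairs`, `sd_ref`.
#' @examples
#' x <- simulate_white_noise(1000, seed = 1)
#' ec <- entropy_curve(x, eps = c(0.1, 0.2, 0.5))
#' ec$k2
#' @export
entropy_curve <- function(x, eps = default_eps_grid(), m = 2, L = 1,
                          min_pairs = 10, eps_units = c("sd", "absolute"),
                          scale_sd = NULL, theiler = 0, dt = 1) {
  v <- ts_values(x)
  eps <- as.numeric(eps)
  eps_units <- match.arg(eps_units)
  if (any(eps <= 0) || is.unsorted(eps, strictly = TRUE))
    stop("`eps` must be a strictly ascending positive grid", call. = FALSE)
  if (eps_units == "sd") {
    sd_ref <- if (is.null(scale_sd)) sd(v) else as.numeric(scale_sd)
    if (!is.finite(sd_ref) || sd_ref <= 0)
      stop("degenerate series: zero standard deviation, cannot form SD-relative scales",
           call. = FALSE)
    eps_abs <- eps * sd_ref
  } else {
    sd_ref <- NA_real_
    eps_abs <- eps
  }
  res <- pair_counts_dual(v, as.integer(m), as.integer(L), eps_abs,
                          as.integer(theiler))
  cm <- res$counts_m / res$n_pairs
  cm1 <- res$counts_m1 / res$n_pairs
  defined <- res$counts_m >= min_pairs & res$counts_m1 >= min_pairs
  k2 <- ifelse(defined, (log(cm) - log(cm1)) / (L * dt), NA_real_)
  bs <- if (inherits(x, "coarse_grained")) x$block_size else 1L
  structure(list(eps = eps, eps_abs = eps_abs, k2 = k2,
                 pairs_m = res$counts_m, pairs_m1 = res$counts_m1,
                 n_pairs = res$n_pairs, m = as.integer(m), L = as.integer(L),
                 block_size = bs, eps_units = eps_units,
                 min_pairs = min_pairs, sd_ref = sd_ref, n = length(v)),
            class = "entropy_curve")
}

#' Default logarithmic scale grid
#'
#' Log-spaced grid of scales, by default 30 points from 0.05 to 1 (in
#' SD-fraction units), matching common sample-entropy practice where the
#' tolerance is a fraction of the signal's standard deviation.
#'
#' @param from,to Grid end points (positive).
#' @param length.out Number of grid points.
#' @return Strictly ascending numeric vector.
#' @export
default_eps_grid <- function(from = 0.05, to = 1, length.out = 30) {
  exp(seq(log(from), log(to), length.out = length.out))
}

#' Sample entropy / K2 at a single scale
#'
#' Convenience wrapper around [entropy_curve()] for one scale; returns
#' `NA` (undefined) when the pair counts fall below `min_pairs`.
#'
#' @inheritParams entropy_curve
#' @param eps A single positive scale.
#' @return A single K2 value in nats per sample, or `NA` if undefined.
#' @export
k2_at_scale <- function(x, eps, m = 2, L = 1, min_pairs = 10,
                        eps_units = c("sd", "absolute"), scale_sd = NULL,
                        theiler = 0, dt = 1) {
  stopifnot(length(eps) == 1L)
  entropy_curve(x, eps, m = m, L = L, min_pairs = min_pairs,
                eps_units = eps_units, scale_sd = scale_sd,
                theiler = theiler, dt = dt)$k2
}

#' Multiscale entropy surface K2^(bs)(eps)
#'
#' Computes the K2 curve of the coarse-grained series for every block size:
#' entry `(bs, eps)` is the correlation entropy of `coarse_grain(x, bs)` at
#' scale `eps`.  Crucially, the scale grid is held fixed in the ORIGINAL
#' series' units across all rows (SD fractions refer to `sd(x)`, never to
#' the smoothed series): the bi-scaling law
#' \eqn{K_2^{(b_s)}(\varepsilon) \sim (H-1)\ln b_s - \ln\varepsilon}
#' arises precisely because the smoothed variance shrinks under a fixed
#' absolute scale.
#'
#' @inheritParams entropy_curve
#' @param block_sizes Ascending vector of block sizes (default 1:10).
#' @return An `mse_surface` object: `block_sizes`, `eps`, `eps_abs`, `k2`
#'   (matrix block x scale), `pairs_m`, `pairs_m1`, `m`, `L`, `min_pairs`,
#'   `sd_ref`.
#' @examples
#' x <- simulate_white_noise(2000, seed = 1)
#' s <- mse_surface(x, block_sizes = c(1, 2, 4), eps = c(0.2, 0.5))
#' s$k2
#' @export
mse_surface <- function(x, block_sizes = 1:10, eps = default_eps_grid(),
                        m = 2, L = 1, min_pairs = 10,
                        eps_units = c("sd", "absolute"), theiler = 0, dt = 1) {
  v <- ts_values(x)
  eps_units <- match.arg(eps_units)
  bs <- sort(unique(as.integer(block_sizes)))
  if (any(is.na(bs)) || any(bs < 1L)) stop("invalid block sizes", call. = FALSE)
  sd0 <- sd(v)
  if (eps_units == "sd" && (!is.finite(sd0) || sd0 <= 0))
    stop("degenerate series: zero standard deviation", call. = FALSE)
  eps <- as.numeric(eps)
  nG <- length(eps)
  k2 <- matrix(NA_real_, nrow = length(bs), ncol = nG,
               dimnames = list(paste0("bs", bs), signif(eps, 6)))
  pm <- k2; pm1 <- k2
  for (i in seq_along(bs)) {
    cg <- coarse_grain(v, bs[i])
    cg$block_size <- bs[i]
    ec <- entropy_curve(cg, eps, m = m, L = L, min_pairs = min_pairs,
                        eps_units = eps_units,
                        scale_sd = if (eps_units == "sd") sd0 else NULL,
                        theiler = theiler, dt = dt)
    k2[i, ] <- ec$k2
    pm[i, ] <- ec$pairs_m
    pm1[i, ] <- ec$pairs_m1
  }
  structure(list(block_sizes = bs, eps = eps,
                 eps_abs = if (eps_units == "sd") eps * sd0 else eps,
                 k2 = k2, pairs_m = pm, pairs_m1 = pm1,
                 m = as.integer(m), L = as.integer(L), min_pairs = min_pairs,
                 eps_units = eps_units, sd_ref = sd0, n = length(v)),
            class = "mse_surface")
}

#' @export
print.entropy_curve <- function(x, ...) {
  nd <- sum(is.finite(x$k2))
  cat(sprintf("<entropy_curve> m = %d, L = %d, bs = %d, n = %d; %d/%d scales defined\n",
              x$m, x$L, x$block_size, x$n, nd, length(x$eps)))
  if (nd > 0)
    cat(sprintf("  eps in [%.4g, %.4g] (%s units), K2 in [%.4g, %.4g]\n",
                min(x$eps[is.finite(x$k2)]), max(x$eps[is.finite(x$k2)]),
                x$eps_units, min(x$k2, na.rm = TRUE), max(x$k2, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.mse_surface <- function(x, ...) {
  cat(sprintf("<mse_surface> %d block sizes x %d scales, m = %d, n = %d (%s units)\n",
              length(x$block_sizes), length(x$eps), x$m, x$n, x$eps_units))
  invisible(x)
}

#' Tidy data frame view of an MSE surface
#'
#' @param x An `mse_surface`.
#' @param ... Unused.
#' @return Data frame with columns `block_size`, `eps`, `k2`, `pairs_m`,
#'   `pairs_m1`.
#' @export
as.data.frame.mse_surface <- function(x, ...) {
  data.frame(block_size = rep(x$block_sizes, times = length(x$eps)),
             eps = rep(x$eps, each = length(x$block_sizes)),
             k2 = as.vector(x$k2),
             pairs_m = as.vector(x$pairs_m),
             pairs_m1 = as.vector(x$pairs_m1))
}
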