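# Independent brute-force oracles, deliberately naive (double loops over
# explicit delay vectors) so they share no code path with the package's
# optimized correlation sums.

# Chebyshev distance between delay vectors i and j of dimension m, delay L
oracle_cheb <- function(x, i, j, m, L) {
  max(abs(x[i + (0:(m - 1)) * L] - x[j + (0:(m - 1)) * L]))
}

# Correlation integral over all N - (m-1)L delay vectors (self-pairs excluded)
oracle_corr_integral <- function(x, m, L, eps) {
  nv <- length(x) - (m - 1) * L
  cnt <- 0
  for (i in 1:(nv - 1)) for (j in (i + 1):nv)
    if (oracle_cheb(x, i, j, m, L) <= eps) cnt <- cnt + 1
  cnt / (nv * (nv - 1) / 2)
}

# Matched-template pair counts at dimensions m and m+1 over the same
# nv = N - m*L templates (the sample-entropy convention)
oracle_dual_counts <- function(x, m, L, eps) {
  nv <- length(x) - m * L
  cm <- 0; cm1 <- 0
  for (i in 1:(nv - 1)) for (j in (i + 1):nv) {
    if (oracle_cheb(x, i, j, m, L) <= eps) cm <- cm + 1
    if (oracle_cheb(x, i, j, m + 1, L) <= eps) cm1 <- cm1 + 1
  }
  list(cm = cm, cm1 = cm1, n_pairs = nv * (nv - 1) / 2)
}

oracle_k2 <- function(x, m, L, eps) {
  d <- oracle_dual_counts(x, m, L, eps)
  (log(d$cm / d$n_pairs) - log(d$cm1 / d$n_pairs)) / L
}

# Log-log periodogram regression slope (frequency bins 2..kmax).  A Hann
# taper and a low-frequency cut are needed for steep (nonstationary walk)
# spectra, where plain-periodogram leakage caps the measurable slope at -2.
oracle_periodogram_slope <- function(x, kmax = NULL, hann = FALSE) {
  x <- k2mse::ts_values(x)
  n <- length(x)
  x <- x - mean(x)
  if (hann) x <- x * (0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  p <- Mod(fft(x))^2 / n
  k <- 2:(if (is.null(kmax)) n %/% 2 else kmax)
  f <- (k - 1) / n
  unname(coef(lm(log(p[k]) ~ log(f)))[2])
}

# Hand-built entropy_curve fixture (for fit/feature tests)
make_curve <- function(eps, k2, m = 2, min_pairs = 10) {
  structure(list(eps = eps, eps_abs = eps, k2 = k2,
                 pairs_m = ifelse(is.finite(k2), 1000, 0),
                 pairs_m1 = ifelse(is.finite(k2), 1000, 0),
                 n_pairs = 10000, m = m, L = 1L, block_size = 1L,
                 eps_units = "absolute", min_pairs = min_pairs,
                 sd_ref = NA_real_, n = 1000L),
            class = "entropy_curve")
}
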