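test_that("delay embedding produces the expected vectors and counts", {
  e <- embed_series(c(1, 2, 3), m = 2)
  expect_equal(e, rbind(c(1, 2), c(2, 3)))
  expect_equal(embed_series(1:5, m = 1), matrix(1:5, ncol = 1))
  expect_equal(nrow(embed_series(rnorm(4097), m = 5, L = 1)), 4093)
  expect_equal(nrow(embed_series(1:20, m = 3, L = 4)), 12)
  expect_error(embed_series(1:4, m = 5), "too short")
})

test_that("correlation integral saturates at 1 and counts ties as within eps", {
  x <- c(0, 1, 0.5, 1.5, 0.2)
  expect_equal(correlation_integral(x, eps = 2, m = 2), 1)
  # two identical vectors at distance exactly 0, plus a tie at exactly eps
  expect_equal(correlation_integral(c(1, 2, 1, 2), eps = 1e-9, m = 2), 1 / 3)
  expect_equal(correlation_integral(c(0, 0, 1), eps = 1, m = 1), 1)
  expect_error(correlation_integral(x, eps = -1), "positive")
})

test_that("optimized correlation integral equals the naive double-loop oracle exactly", {
  for (n in c(10, 50, 200)) {
    x <- ts_values(simulate_white_noise(n, seed = n))
    for (m in c(1, 2, 5, 6)) {
      for (eps in c(0.1, 0.5, 1, 2.5)) {
        expect_identical(correlation_integral(x, eps, m = m),
                         oracle_corr_integral(x, m, 1, eps))
      }
    }
  }
})

test_that("K2 at a scale matches the brute-force computation of both sums exactly", {
  x <- ts_values(simulate_fgn(0.7, 10, seed = 1))
  for (eps in c(0.3, 0.8, 1.5)) {
    got <- k2_at_scale(x, eps, m = 2, min_pairs = 1, eps_units = "absolute")
    d <- oracle_dual_counts(x, 2, 1, eps)
    if (d$cm >= 1 && d$cm1 >= 1) {
      expect_identical(got, oracle_k2(x, 2, 1, eps))
    } else {
      expect_true(is.na(got))   # no matching pairs: flagged, not zero
    }
  }
  # with a delay larger than 1 as well
  y <- ts_values(simulate_white_noise(30, seed = 2))
  expect_identical(k2_at_scale(y, 0.7, m = 2, L = 3, min_pairs = 1,
                               eps_units = "absolute"),
                   oracle_k2(y, 2, 3, 0.7))
})

test_that("constant series has zero correlation entropy", {
  expect_equal(k2_at_scale(rep(2, 50), eps = 0.5, m = 2, min_pairs = 1,
                           eps_units = "absolute"), 0)
})

test_that("correlation sums are monotone and K2 is non-negative where defined", {
  for (s in 1:5) {
    x <- ts_values(simulate_fgn(0.2 + 0.15 * s, 300, seed = s))
    ec <- entropy_curve(x, default_eps_grid(0.02, 2, 25), m = 3, min_pairs = 1)
    expect_true(all(diff(ec$pairs_m) >= 0))
    expect_true(all(diff(ec$pairs_m1) >= 0))
    expect_true(all(ec$pairs_m1 <= ec$pairs_m))
    expect_true(all(ec$k2[is.finite(ec$k2)] >= 0))
    cv <- correlation_integral(x, ec$eps * sd(x), m = 3)
    expect_true(all(diff(cv) >= 0))
  }
})

test_that("scales below min_pairs resolvability are flagged NA, not zero", {
  x <- ts_values(simulate_white_noise(60, seed = 8))
  ec <- entropy_curve(x, c(0.001, 0.5), m = 2, min_pairs = 10)
  expect_true(is.na(ec$k2[1]))
  expect_true(is.finite(ec$k2[2]))
})

test_that("white-noise K2 grows like -ln eps at small scales", {
  x <- simulate_white_noise(4096, seed = 2)
  f <- fit_eps_scaling(entropy_curve(x, default_eps_grid(0.05, 0.5, 12), m = 2))
  expect_equal(f$slope, -1, tolerance = 0.2)
})

test_that("the bs = 1 row of the MSE surface equals the raw-series entropy curve", {
  x <- simulate_fgn(0.7, 1024, seed = 6)
  g <- default_eps_grid(0.1, 1, 8)
  surf <- mse_surface(x, block_sizes = c(1, 2, 5), eps = g, m = 2)
  ec <- entropy_curve(x, g, m = 2)
  expect_equal(unname(surf$k2[1, ]), ec$k2)
  expect_true(all(surf$k2[is.finite(surf$k2)] >= 0))
})

test_that("fGn MSE surface obeys the scale-shift self-similarity relation", {
  # smoothing by bs rescales phase-space scales by bs^(H-1): the bs = 10
  # curve read at eps * 10^(H-1) reproduces the raw curve at eps
  H <- 0.7
  x <- simulate_fgn(H, 2^14, seed = 11)
  g <- default_eps_grid(0.1, 0.6, 10)
  sd0 <- sd(ts_values(x))
  raw <- entropy_curve(x, g, m = 2)
  sm <- entropy_curve(coarse_grain(x, 10), g * 10^(H - 1) * sd0, m = 2,
                      eps_units = "absolute")
  d <- abs(sm$k2 - raw$k2)
  expect_lt(mean(d[is.finite(d)]), 0.1)
})

test_that("Theiler window excludes temporally adjacent pairs", {
  x <- ts_values(simulate_white_noise(40, seed = 3))
  c0 <- correlation_integral(x, 0.5, m = 2, theiler = 0)
  c5 <- correlation_integral(x, 0.5, m = 2, theiler = 5)
  nv <- 39
  cnt0 <- c0 * nv * (nv - 1) / 2
  # oracle with the window: drop pairs closer than 6 apart
  cnt <- 0
  for (i in 1:(nv - 1)) for (j in (i + 1):nv)
    if (j - i > 5 && oracle_cheb(x, i, j, 2, 1) <= 0.5) cnt <- cnt + 1
  expect_equal(c5, cnt / ((nv - 5) * (nv - 6) / 2))
  expect_lte(cnt, cnt0)
})
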