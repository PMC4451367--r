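test_that("an exact K2 = -ln(eps) curve is recovered with zero fit error", {
  g <- default_eps_grid(0.05, 1, 20)
  cv <- make_curve(g, -log(g))
  f <- fit_eps_scaling(cv)
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_equal(f$fit_error_pct, 0, tolerance = 1e-10)
  expect_equal(f$n_points, 20)
  # a shifted/scaled exact line too
  f2 <- fit_eps_scaling(make_curve(g, 2.5 - 0.7 * log(g)))
  expect_equal(f2$slope, -0.7, tolerance = 1e-12)
  expect_equal(f2$intercept, 2.5, tolerance = 1e-12)
})

test_that("fits on too few defined points are rejected", {
  g <- c(0.1, 0.2, 0.4)
  expect_error(fit_eps_scaling(make_curve(g, c(1, NA, NA))), "fewer than 3")
  expect_error(fit_eps_scaling(make_curve(default_eps_grid(0.05, 1, 10),
                                          -log(default_eps_grid(0.05, 1, 10))),
                               eps_range = c(0.05, 0.07)),
               "fewer than 3")
})

test_that("simulated fGn has |slope| close to 1 in the small-scale region", {
  x <- simulate_fgn(0.7, 2^13, seed = 21)
  f <- fit_eps_scaling(entropy_curve(x, default_eps_grid(0.05, 0.5, 12), m = 2))
  expect_equal(abs(f$slope), 1, tolerance = 0.2)
})

test_that("epsilon* is the smallest scale at which K2 is defined", {
  g <- default_eps_grid(0.05, 1, 10)
  expect_equal(epsilon_star(make_curve(g, -log(g))), g[1])
  k2 <- -log(g); k2[1:4] <- NA
  expect_equal(epsilon_star(make_curve(g, k2)), g[5])
  expect_error(epsilon_star(make_curve(g, rep(NA_real_, 10))), "no resolvable")
})

test_that("a larger noise floor pushes epsilon* upward", {
  base <- ts_values(simulate_fgn(0.7, 2048, seed = 31))
  spikes <- ts_values(simulate_white_noise(2048, seed = 32))
  spiky <- base + 8 * spikes * (abs(spikes) > 2)   # intermittent large shocks
  g <- default_eps_grid(0.005, 1, 30) * sd(base)
  es_clean <- epsilon_star(entropy_curve(base, g, m = 2, eps_units = "absolute"))
  es_spiky <- epsilon_star(entropy_curve(spiky, g, m = 2, eps_units = "absolute"))
  expect_gte(es_spiky, es_clean)
})

test_that("the 6-point fit error is zero on perfect scaling and positive at a knee", {
  g <- default_eps_grid(0.05, 1, 12)
  expect_equal(fit_error_feature(make_curve(g, 1 - log(g))), 0, tolerance = 1e-10)
  kneed <- 1 - log(g); kneed[4:12] <- kneed[4] - 0.2 * (log(g)[4:12] - log(g)[4])
  expect_gt(fit_error_feature(make_curve(g, kneed)), 0.5)
  expect_error(fit_error_feature(make_curve(g[1:4], 1 - log(g[1:4])), n_points = 6),
               "defined scales")
})

test_that("heavy intermittent noise degrades the scaling-fit error of fGn", {
  base <- ts_values(simulate_fgn(0.7, 2048, seed = 41))
  w <- ts_values(simulate_white_noise(2048, seed = 42))
  noisy <- base + 20 * w * (abs(w) > 1.8)
  g <- default_eps_grid(0.05, 1, 20)
  fe_clean <- fit_error_feature(entropy_curve(base, g, m = 2))
  fe_noisy <- fit_error_feature(entropy_curve(noisy, g, m = 2))
  expect_lt(fe_clean, fe_noisy)
})

test_that("block-size scaling turns surfaces into Hurst estimates", {
  # constant rows: slope 0, h_hat 1
  surf <- mse_surface(simulate_white_noise(2000, seed = 51), 1:6,
                      eps = c(0.2, 0.5), m = 2)
  surf$k2[] <- 1.3
  f <- fit_bs_scaling(surf, 0.2, bs_range = c(1, 6))
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_equal(f$h_hat, 1, tolerance = 1e-12)
  # undefined entries are reported by block size
  surf$k2[, 1] <- NA
  surf$k2[1:2, 1] <- 1
  expect_error(fit_bs_scaling(surf, 0.2, bs_range = c(1, 6)), "block sizes")
})

test_that("white-noise block-size slope is near -1/2", {
  slopes <- sapply(1:3, function(s)
    fit_bs_scaling(mse_surface(simulate_white_noise(2^13, seed = s),
                               1:10, eps = 0.2, m = 2), 0.2)$slope)
  expect_lt(abs(mean(slopes) - (-0.5)), 0.1)
})

test_that("Hurst recovery across H and stability across the scale used", {
  for (H in c(0.2, 0.5, 0.8)) {
    hh <- sapply(1:3, function(s) {
      x <- simulate_fgn(H, 2^13, seed = 60 + s)
      fit_bs_scaling(mse_surface(x, 1:10, eps = 0.2, m = 2), 0.2)$h_hat
    })
    expect_lt(abs(mean(hh) - H), 0.1)
  }
  # eps enters the bi-scaling law only through the intercept
  x <- simulate_fgn(0.7, 2^14, seed = 70)
  s <- mse_surface(x, 1:10, eps = c(0.15, 0.25), m = 2)
  h1 <- fit_bs_scaling(s, 0.15)$h_hat
  h2 <- fit_bs_scaling(s, 0.25)$h_hat
  expect_lt(abs(h1 - h2), 0.05)
})
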