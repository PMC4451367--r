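# Synthetic RR-interval analog: baseline + persistent fGn fluctuation,
# quantized to the resolution of a 128 Hz ECG clock (RR intervals derived
# from sampled ECG are multiples of the sampling period).  `amp` is the
# fluctuation SD in seconds; a small amp relative to the clock quantum is
# the low-variability (heart-failure-like) regime.
make_rr <- function(amp, seed, n = 3000, fs = 128) {
  base <- 0.8 + amp * ts_values(simulate_fgn(0.75, n, seed = seed))
  round(base * fs) / fs
}

test_that("HRV features are deterministic and difference exactly once", {
  rr <- make_rr(0.05, 1)
  f1 <- hrv_features(rr, record_id = "a")
  f2 <- hrv_features(rr, record_id = "a")
  expect_identical(f1, f2)
  expect_identical(f1$preprocessing, "differenced")
  expect_equal(f1$n_used, 3000)
})

test_that("HRV records longer than the cap are truncated to its first samples", {
  rr <- make_rr(0.05, 2, n = 1500)
  f_cap <- hrv_features(rr, max_points = 1200)
  f_direct <- hrv_features(rr[1:1200])
  expect_equal(f_cap$eps_star, f_direct$eps_star)
  expect_equal(f_cap$n_used, 1200)
})

test_that("degenerate or too-short RR series are rejected", {
  expect_error(suppressWarnings(hrv_features(rep(0.8, 2000))), "degenerate")
  expect_error(suppressWarnings(hrv_features(c(0.8, 0.9, 1.0, 0.7))), "too short")
  expect_warning(hrv_features(make_rr(0.05, 3, n = 900)), "unreliable")
})

test_that("reduced amplitude lowers the resolvable scale in absolute units", {
  y <- ts_values(difference(make_rr(0.05, 4)))
  g <- default_eps_grid(0.0005, 0.1, 30)
  es_full <- epsilon_star(entropy_curve(y, g, m = 5, eps_units = "absolute"))
  es_small <- epsilon_star(entropy_curve(0.2 * y, g, m = 5, eps_units = "absolute"))
  expect_lt(es_small, es_full)
})

test_that("disjoint noise floors let epsilon* separate two synthetic groups", {
  healthy <- lapply(1:4, function(s)
    hrv_features(make_rr(0.05, s), record_id = sprintf("h%02d", s)))
  low_var <- lapply(1:4, function(s)
    hrv_features(make_rr(0.006, 100 + s), record_id = sprintf("c%02d", s)))
  gs <- group_summary(c(healthy, low_var),
                      rep(c("healthy", "low_var"), each = 4))
  expect_true(gs$separation[["eps_star"]])
  sm <- gs$summary[gs$summary$feature == "eps_star", ]
  expect_gt(sm$mean[sm$group == "healthy"], sm$mean[sm$group == "low_var"])
})

test_that("EEG features at bs = 1 reduce to plain sample entropy", {
  x <- random_walk(simulate_fgn(0.6, 2049, seed = 7))
  f <- suppressWarnings(eeg_features(x, eps = 0.2, block_sizes = 1))
  direct <- k2_at_scale(diff(ts_values(x)), 0.2, m = 2)
  expect_equal(f$k2_at[["bs=1,eps=0.2"]], direct)
  expect_identical(f$preprocessing, "differenced")
})

test_that("differencing a random-walk record defines more feature cells than raw", {
  rw <- random_walk(simulate_fgn(0.3, 2049, seed = 5))
  fr <- suppressWarnings(eeg_features(rw, eps = c(0.05, 0.2),
                                      block_sizes = c(2, 15), preprocess = "raw"))
  fd <- suppressWarnings(eeg_features(rw, eps = c(0.05, 0.2),
                                      block_sizes = c(2, 15)))
  expect_gt(sum(is.finite(unlist(fd$k2_at))), sum(is.finite(unlist(fr$k2_at))))
})

test_that("every requested (bs, eps) cell is present in the feature vector", {
  x <- random_walk(simulate_fgn(0.5, 4097, seed = 8))
  f <- suppressWarnings(eeg_features(x, eps = c(0.05, 0.2), block_sizes = c(2, 15)))
  expect_setequal(names(f$k2_at),
                  c("bs=2,eps=0.05", "bs=2,eps=0.2",
                    "bs=15,eps=0.05", "bs=15,eps=0.2"))
})

test_that("group-mean Hurst estimates order with the generating H", {
  feats <- list(); labels <- character(0)
  for (H in c(0.2, 0.5, 0.8)) for (s in 1:3) {
    feats <- c(feats, list(suppressWarnings(
      eeg_features(random_walk(simulate_fgn(H, 4097, seed = 200 + s))))))
    labels <- c(labels, sprintf("H%.1f", H))
  }
  gs <- group_summary(feats, labels)
  hm <- gs$summary[gs$summary$feature == "h_hat", ]
  hm <- hm[order(hm$group), ]
  expect_true(all(diff(hm$mean) > 0))
})

test_that("group_summary flags identical groups as non-separating and validates input", {
  f <- hrv_features(make_rr(0.05, 9))
  gs <- group_summary(list(f, f, f, f), c("a", "a", "b", "b"))
  expect_false(any(gs$separation))
  expect_error(group_summary(list(f, f), "a"), "length")
  expect_error(group_summary(list(f, f), c("a", "a")), "2 groups")
  expect_error(group_summary(list(f, 1), c("a", "b")), "feature_vector")
})
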