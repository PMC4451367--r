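#' Discrimination features for heart-rate-variability recordings
#'
#' Implements the HRV workflow: truncate to the first `max_points`
#' RR intervals, take the increment (first-difference) process — HRV is
#' nonstationary with 1/f structure, its increments are the stationary
#' object — compute the K2(eps) curve at embedding dimension `m`, and
#' extract the smallest resolvable scale ([epsilon_star()]) and the
#' `n_fit_points`-point linear-fit error ([fit_error_feature()]).  A Hurst
#' estimate from the block-size scaling at `eps = 0.2` SD is included when
#' `compute_hurst = TRUE`.
#'
#' @param x RR-interval series (seconds), `time_series` or numeric.
#' @param m Embedding dimension (default 5, the HRV setting).
#' @param n_fit_points Scales in the fit-error window (default 6).
#' @param eps Scale grid, as fractions of the differenced record's SD.
#' @param min_pairs Pair-count threshold defining resolvability.
#' @param max_points Truncate longer records to this many samples
#'   (default 30000).
#' @param compute_hurst Also estimate H from block-size scaling (bs 1..10).
#' @param record_id Identifier carried into the output.
#' @return A `feature_vector`: `record_id`, `eps_star`, `fit_error_pct`,
#'   `k2_at` (named list), `h_hat`, `preprocessing`, `n_used`.
#' @export
hrv_features <- function(x, m = 5, n_fit_points = 6,
                         eps = default_eps_grid(0.01, 1, 40),
                         min_pairs = 10, max_points = 30000,
                         compute_hurst = TRUE, record_id = "") {
  v <- ts_values(x)
  if (length(v) > max_points) v <- v[seq_len(max_points)]
  if (length(v) < 1000)
    warning(sprintf("only %d samples; HRV features are unreliable below ~1000",
                    length(v)))
  if (length(v) <= (m + 1))
    stop(sprintf("series too short (n = %d) for m = %d embedding", length(v), m),
         call. = FALSE)
  y <- diff(v)
  if (!isTRUE(sd(y) > 0))
    stop("degenerate RR series: increments have zero variance", call. = FALSE)
  curve <- entropy_curve(y, eps, m = m, L = 1, min_pairs = min_pairs,
                         eps_units = "sd")
  es <- epsilon_star(curve)
  fe <- fit_error_feature(curve, n_points = n_fit_points)
  h_hat <- NA_real_
  if (compute_hurst) {
    surf <- mse_surface(y, block_sizes = 1:10, eps = 0.2, m = 2, L = 1,
                        min_pairs = min_pairs, eps_units = "sd")
    h_hat <- tryCatch(fit_bs_scaling(surf, 0.2)$h_hat,
                      error = function(e) NA_real_)
  }
  k2_at <- stats::setNames(as.list(curve$k2), sprintf("bs=1,eps=%g", curve$eps))
  structure(list(record_id = record_id, eps_star = es, fit_error_pct = fe,
                 k2_at = k2_at, h_hat = h_hat, preprocessing = "differenced",
                 n_used = length(v), m = m, curve = curve),
            class = "feature_vector")
}

#' Discrimination features for EEG-like recordings
#'
#' Implements the EEG workflow: optionally difference the record (EEG
#' behaves like a random-walk process, so its increments are the
#' stationary object and separate groups better), then read the MSE
#' surface \eqn{K_2^{(b_s)}(\varepsilon)} at the requested block sizes and
#' scales — the defaults `eps = (0.2, 0.05)` and `block_sizes = (2, 15)`
#' are the discriminative settings for the three-group seizure problem.
#' Scales are fractions of the (possibly differenced) record's SD.  A
#' Hurst estimate from block sizes 1..10 at the first scale is attached.
#'
#' @param x EEG-like series (`time_series` or numeric, ~4097 points typical).
#' @param eps Scales (SD fractions) at which to report K2.
#' @param block_sizes Block sizes at which to report K2.
#' @param m Embedding dimension (default 2).
#' @param preprocess `"differenced"` (default) or `"raw"`.
#' @param min_pairs Pair-count threshold.
#' @param record_id Identifier carried into the output.
#' @return A `feature_vector` with `k2_at[["bs=B,eps=E"]]` entries (NA when
#'   undefined at that cell), `eps_star`, `fit_error_pct`, `h_hat`.
#' @export
eeg_features <- function(x, eps = c(0.2, 0.05), block_sizes = c(2, 15),
                         m = 2, preprocess = c("differenced", "raw"),
                         min_pairs = 10, record_id = "") {
  preprocess <- match.arg(preprocess)
  v <- ts_values(x)
  if (preprocess == "differenced") v <- diff(v)
  if (!isTRUE(sd(v) > 0)) stop("degenerate series: zero variance", call. = FALSE)
  block_sizes <- sort(unique(as.integer(block_sizes)))
  bs_all <- sort(unique(c(1:10, block_sizes)))
  if (length(v) %/% max(bs_all) < 2L)
    stop(sprintf("block size %d too large for %d samples", max(bs_all), length(v)),
         call. = FALSE)
  if (length(v) %/% max(bs_all) < 250L)
    warning(sprintf("largest block size leaves only %d samples; K2 there is noisy",
                    length(v) %/% max(bs_all)))
  eps <- sort(as.numeric(eps), decreasing = FALSE)
  surf <- mse_surface(v, block_sizes = bs_all, eps = unique(eps), m = m, L = 1,
                      min_pairs = min_pairs, eps_units = "sd")
  k2_at <- list()
  for (b in block_sizes) for (e in eps) {
    i <- match(b, surf$block_sizes); j <- match(e, surf$eps)
    k2_at[[sprintf("bs=%d,eps=%g", b, e)]] <- surf$k2[i, j]
  }
  curve <- entropy_curve(v, default_eps_grid(0.02, 1, 30), m = m, L = 1,
                         min_pairs = min_pairs, eps_units = "sd")
  es <- tryCatch(epsilon_star(curve), error = function(e) NA_real_)
  fe <- tryCatch(fit_error_feature(curve), error = function(e) NA_real_)
  h_hat <- tryCatch(fit_bs_scaling(surf, max(eps), bs_range = c(1, 10))$h_hat,
                    error = function(e) NA_real_)
  structure(list(record_id = record_id, eps_star = es, fit_error_pct = fe,
                 k2_at = k2_at, h_hat = h_hat, preprocessing = preprocess,
                 n_used = length(v), m = m, surface = surf),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s(%s): eps* = %.4g, fit error = %.3g%%, h_hat = %.3g\n",
              if (nzchar(x$record_id)) x$record_id else "record",
              x$preprocessing, x$eps_star, x$fit_error_pct, x$h_hat))
  invisible(x)
}

# numeric feature columns of one feature_vector
fv_row <- function(f) {
  base <- c(eps_star = f$eps_star, fit_error_pct = f$fit_error_pct,
            h_hat = f$h_hat)
  k2 <- unlist(f$k2_at)
  c(base, k2)
}

#' Per-group summary and separation of discrimination features
#'
#' Tabulates mean, SD and range of each numeric feature per group, and
#' flags, per feature, whether the observed group ranges are pairwise
#' disjoint — the criterion behind a feature "completely separating"
#' clinical groups (no threshold-free overlap).
#'
#' @param features A list of `feature_vector`s (see [hrv_features()],
#'   [eeg_features()]).
#' @param grouping Group labels, one per feature vector (>= 2 groups).
#' @return A `group_summary`: `$summary` data frame (feature, group, n,
#'   mean, sd, min, max) and `$separation`, a named logical vector per
#'   feature.
#' @export
group_summary <- function(features, grouping) {
  stopifnot(is.list(features), length(features) == length(grouping))
  if (!all(vapply(features, inherits, logical(1), "feature_vector")))
    stop("`features` must be a list of feature_vector objects", call. = FALSE)
  g <- factor(grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  rows <- lapply(features, fv_row)
  feats <- Reduce(intersect, lapply(rows, names))
  mat <- do.call(rbind, lapply(rows, function(r) r[feats]))
  out <- list()
  sep <- logical(0)
  for (f in feats) {
    vals <- mat[, f]
    by_g <- split(vals, g)
    st <- do.call(rbind, lapply(names(by_g), function(lv) {
      v <- by_g[[lv]][is.finite(by_g[[lv]])]
      data.frame(feature = f, group = lv, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_)
    }))
    out[[f]] <- st
    # pairwise range disjointness; undefined values disqualify separation
    ranges <- lapply(by_g, function(v) if (all(is.finite(v)) && length(v)) range(v) else NULL)
    ok <- !any(vapply(ranges, is.null, logical(1)))
    if (ok) {
      lv <- names(ranges)
      for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
        ra <- ranges[[a]]; rb <- ranges[[b]]
        if (max(ra[1], rb[1]) <= min(ra[2], rb[2])) ok <- FALSE
      }
    }
    sep[f] <- ok
  }
  structure(list(summary = do.call(rbind, out), separation = sep,
                 groups = levels(g)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d groups (%s)\n", length(x$groups),
              paste(x$groups, collapse = ", ")))
  sepf <- names(x$separation)[x$separation]
  cat("  completely separating features:",
      if (length(sepf)) paste(sepf, collapse = ", ") else "(none)", "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
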