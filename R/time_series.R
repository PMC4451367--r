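#' Construct a uniformly sampled time series
#'
#' Light container for a univariate, uniformly sampled real-valued signal.
#' All analysis functions in the package accept either a `time_series`
#' object or a bare numeric vector (treated as `dt = 1`).
#'
#' @param values Numeric vector of finite samples, length >= 2.
#' @param dt Positive sampling interval (seconds per sample; default 1).
#' @param label Free-text description carried through for provenance.
#' @param seed Seed the values were generated from, if any (provenance only).
#' @return An object of class `time_series` with fields `values`, `dt`,
#'   `label` and `seed`.
#' @examples
#' x <- time_series(sin(1:100 / 5), dt = 0.01, label = "toy")
#' length(ts_values(x))
#' @export
time_series <- function(values, dt = 1, label = "", seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("time series values must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  structure(list(values = values, dt = dt, label = as.character(label)[1L],
                 seed = seed),
            class = "time_series")
}

#' Coerce to a time series
#'
#' @param x A `time_series` or numeric vector.
#' @param ... Passed to [time_series()] for numeric input.
#' @return A `time_series` object.
#' @export
as_time_series <- function(x, ...) {
  if (inherits(x, "time_series")) return(x)
  time_series(x, ...)
}

#' Extract the sample values of a time series
#'
#' @param x A `time_series` or numeric vector.
#' @return Numeric vector of samples.
#' @export
ts_values <- function(x) {
  if (inherits(x, "time_series")) x$values else as.numeric(x)
}

ts_dt <- function(x) if (inherits(x, "time_series")) x$dt else 1

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> n = %d, dt = %g%s\n", length(x$values), x$dt,
              if (nzchar(x$label)) paste0(", label = \"", x$label, "\"") else ""))
  cat("  values: ", paste(signif(head(x$values, 6L), 5), collapse = ", "),
      if (length(x$values) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)
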