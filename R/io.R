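#' Read a single-column numeric series from a text file
#'
#' Accepts plain-text / CSV files with one sample per row (optionally more
#' columns, whitespace- or comma-separated).  Lines starting with
#' `comment_char` are treated as a metadata header; `key=value` entries
#' there (e.g. `# dt=0.00576`, `# label=nsr001`) are parsed into the
#' returned series.  Non-numeric data rows abort with their line numbers.
#'
#' @param path File path.
#' @param column 1-based column to read (default 1).
#' @param comment_char Header/comment prefix (default `"#"`).
#' @return A [time_series].
#' @export
read_series <- function(path, column = 1, comment_char = "#") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  is_comment <- startsWith(trimws(lines), comment_char)
  meta <- list(dt = 1, label = basename(path))
  for (ln in lines[is_comment]) {
    body <- sub(paste0("^\\s*", comment_char, "\\s*"), "", ln)
    kv <- regmatches(body, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", body))[[1]]
    if (length(kv) == 3L) {
      key <- kv[2]; val <- trimws(kv[3])
      if (key == "dt") meta$dt <- suppressWarnings(as.numeric(val))
      else meta[[key]] <- val
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) == 0L)
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  vals <- vapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,;\t ]+")[[1]]
    if (length(fields) < column) return(NA_real_)
    suppressWarnings(as.numeric(fields[column]))
  }, numeric(1))
  bad <- data_idx[!is.finite(vals)]
  if (length(bad))
    stop(sprintf("non-numeric or missing values at line(s) %s of %s",
                 paste(head(bad, 10L), collapse = ", "), path), call. = FALSE)
  time_series(vals, dt = if (is.finite(meta$dt) && meta$dt > 0) meta$dt else 1,
              label = meta$label)
}

#' Write a series to a plain-text file with a metadata header
#'
#' One value per line, preceded by `#`-prefixed `key=value` metadata
#' (at least `dt` and `label`), the format [read_series()] parses back.
#'
#' @param x A `time_series` or numeric vector.
#' @param path Output path.
#' @param extra Named character vector of extra header entries.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, extra = NULL) {
  x <- as_time_series(x)
  hdr <- c(sprintf("# dt=%.17g", x$dt), sprintf("# label=%s", x$label))
  if (!is.null(x$seed)) hdr <- c(hdr, sprintf("# seed=%s", format(x$seed)))
  if (!is.null(extra))
    hdr <- c(hdr, sprintf("# %s=%s", names(extra), as.character(extra)))
  writeLines(c(hdr, format(x$values, digits = 17, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Write a results table as TSV or JSON
#'
#' TSV output carries the run configuration as `#`-prefixed header lines
#' before the column header; JSON output nests it under `config` with the
#' rows under `records`.  `read_table_tsv()` reads the TSV form back
#' (round-trip identical within floating-point representation).
#'
#' @param records A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param config Optional named list recorded in the output header.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json"), config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!is.null(config))
      writeLines(sprintf("# %s=%s", names(config),
                         vapply(config, function(v) paste(format(v), collapse = ","),
                                character(1))), con)
    write.table(format(records, digits = 17, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(config = config, records = records), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
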