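#' Validate a scalar time series
#'
#' Checks that `x` is a finite numeric vector of length at least 2 and
#' returns it as a plain numeric vector. All analysis functions in the
#' package accept plain numeric vectors; this helper centralises the
#' contract.
#'
#' @param x numeric vector of uniformly sampled observations.
#' @param min_length minimum admissible length (default 2).
#' @return the validated numeric vector.
#' @export
as_series <- function(x, min_length = 2L) {
  if (is.data.frame(x)) {
    if (ncol(x) != 1L) stop("series data frame must have exactly one column")
    x <- x[[1L]]
  }
  x <- as.numeric(x)
  if (length(x) < min_length) {
    stop(sprintf("series must contain at least %d values, got %d",
                 min_length, length(x)))
  }
  if (!all(is.finite(x))) stop("series contains non-finite values")
  x
}

#' Read a scalar series from disk
#'
#' Accepts either plain text with one number per line or a single-column
#' CSV with an optional header line.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty series file: ", path)
  # drop a non-numeric header if present
  first <- suppressWarnings(as.numeric(lines[[1L]]))
  if (is.na(first)) lines <- lines[-1L]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[[1L]]
    stop(sprintf("non-numeric value on data line %d of %s", bad, path))
  }
  as_series(vals, min_length = 1L)
}

#' Write a scalar series to disk
#'
#' One value per line; with `header` a single header line is prepended
#' (making the file a single-column CSV).
#'
#' @param x numeric vector.
#' @param path destination path.
#' @param header optional column name; `NULL` (default) writes bare numbers.
#' @export
write_series <- function(x, path, header = NULL) {
  x <- as.numeric(x)
  out <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  if (!is.null(header)) out <- c(as.character(header), out)
  writeLines(out, path)
  invisible(path)
}
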