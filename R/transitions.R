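#' Detect transition onsets by a first-difference threshold
#'
#' An onset is a time index `t` (0-based, `t >= 1`) where the absolute
#' first difference `|x[t] - x[t-1]|` exceeds the threshold `theta`.
#' With `signed = "up"` or `"down"` only rises or drops count.
#' Consecutive crossings closer than `min_separation` are thinned,
#' keeping the earliest of each run; the default `min_separation = 1`
#' keeps every crossing.
#'
#' @param x numeric series.
#' @param theta positive threshold on the first difference, in signal units.
#' @param min_separation minimum index distance between retained onsets.
#' @param signed `"abs"` (default), `"up"`, or `"down"`.
#' @return an object of class `transition_set`: list with integer
#'   `onsets` (0-based, strictly increasing) and `theta`.
#' @export
detect_transitions <- function(x, theta, min_separation = 1L,
                               signed = c("abs", "up", "down")) {
  x <- as_series(x)
  signed <- match.arg(signed)
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  min_separation <- as.integer(min_separation)
  stopifnot(min_separation >= 1L)
  d <- diff(x)
  hit <- switch(signed,
                abs = abs(d) > theta,
                up = d > theta,
                down = -d > theta)
  onsets <- which(hit)  # diff index i (1-based) == 0-based onset time
  if (min_separation > 1L && length(onsets) > 1L) {
    keep <- onsets[[1L]]
    for (t in onsets[-1L]) {
      if (t - keep[[length(keep)]] >= min_separation) keep <- c(keep, t)
    }
    onsets <- keep
  }
  structure(list(onsets = as.integer(onsets), theta = theta),
            class = "transition_set")
}

#' Data-driven threshold from a quantile of the first differences
#'
#' Returns the `q`-th quantile of `|diff(x)|`, a fallback when no
#' absolute threshold is known for the signal at hand.
#'
#' @param x numeric series.
#' @param q quantile level in (0, 1), default 0.99.
#' @return threshold in signal units.
#' @export
theta_from_quantile <- function(x, q = 0.99) {
  x <- as_series(x)
  stopifnot(q > 0, q < 1)
  as.numeric(stats::quantile(abs(diff(x)), q, names = FALSE))
}

#' Partition a series into pre-onset (A) and reference (B) windows
#'
#' Every window has length exactly `w`; intervals are half-open and
#' 0-based: `[start, start + w)`. Set A holds, for each onset `t` with at
#' least `w` preceding points, the window `[t - w, t)` ending exactly at
#' the onset. Set B tiles the complement of the exclusion zones
#' `[t - w, t + w)` (length `2w`, onset in the middle): within each
#' maximal admissible segment, windows start at the segment start and
#' advance by `step`, and a final window flush with the segment end is
#' added so data adjacent to an exclusion zone is used.
#'
#' @param series_length total series length.
#' @param transitions a `transition_set` (or integer vector of 0-based onsets).
#' @param w window length, at least 2. Default 100.
#' @param step sliding step for the reference windows, at least 1. Default 20.
#' @return an object of class `window_partition`: list with data frames
#'   `set_A` and `set_B` (columns `start`, `end`; 0-based half-open),
#'   `w`, `step`, and `skipped_onsets`.
#' @export
partition_windows <- function(series_length, transitions, w = 100L,
                              step = 20L) {
  onsets <- if (inherits(transitions, "transition_set")) {
    transitions$onsets
  } else {
    as.integer(transitions)
  }
  series_length <- as.integer(series_length)
  w <- as.integer(w); step <- as.integer(step)
  stopifnot(w >= 2L, step >= 1L, series_length >= 1L)
  if (is.unsorted(onsets, strictly = TRUE)) stop("onsets must be strictly increasing")
  if (length(onsets) > 0L &&
      (onsets[[1L]] < 1L || onsets[[length(onsets)]] >= series_length)) {
    stop("onsets must lie within the series bounds")
  }

  skipped <- onsets[onsets < w]
  if (length(skipped) > 0L) {
    warning(sprintf("%d onset(s) with fewer than w = %d preceding points skipped from set A",
                    length(skipped), w))
  }
  a_onsets <- onsets[onsets >= w]
  set_A <- data.frame(start = a_onsets - w, end = a_onsets)

  # complement of the union of exclusion zones [t - w, t + w), clipped
  excl_lo <- pmax(onsets - w, 0L)
  excl_hi <- pmin(onsets + w, series_length)
  b_starts <- integer(0)
  seg_lo <- 0L
  bounds <- if (length(onsets) > 0L) order(excl_lo) else integer(0)
  for (k in bounds) {
    if (excl_lo[[k]] > seg_lo) {
      b_starts <- c(b_starts, tile_segment(seg_lo, excl_lo[[k]], w, step))
    }
    seg_lo <- max(seg_lo, excl_hi[[k]])
  }
  if (series_length > seg_lo) {
    b_starts <- c(b_starts, tile_segment(seg_lo, series_length, w, step))
  }
  set_B <- data.frame(start = b_starts, end = b_starts + w)

  structure(list(set_A = set_A, set_B = set_B, w = w, step = step,
                 skipped_onsets = as.integer(skipped)),
            class = "window_partition")
}

# window starts covering [lo, hi) with stride `step`, plus a flush-right
# window; returns integer(0) when the segment is shorter than w
tile_segment <- function(lo, hi, w, step) {
  if (hi - lo < w) return(integer(0))
  starts <- seq.int(lo, hi - w, by = step)
  if (starts[[length(starts)]] != hi - w) starts <- c(starts, hi - w)
  as.integer(starts)
}

#' Extract the values of one window from a series
#'
#' @param x numeric series.
#' @param start 0-based inclusive start index.
#' @param end 0-based exclusive end index.
#' @return numeric vector of length `end - start`.
#' @export
window_values <- function(x, start, end) {
  stopifnot(start >= 0L, end <= length(x), end > start)
  x[(start + 1L):end]
}

#' Export a window partition as TSV
#'
#' Three columns: set label (`A`/`B`), 0-based start, exclusive end.
#'
#' @param partition a `window_partition`.
#' @param path destination path.
#' @export
write_partition <- function(partition, path) {
  df <- rbind(
    cbind(set = rep("A", nrow(partition$set_A)), partition$set_A),
    cbind(set = rep("B", nrow(partition$set_B)), partition$set_B)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
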