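#' Multichannel recording with seizure annotations
#'
#' @param signal Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param seizure_intervals Data frame or matrix with columns `start`, `end`:
#'   half-open sample-offset intervals `[start, end)`, 0-based, sorted and
#'   non-overlapping.
#' @return An object of class `recording`.
#' @export
recording <- function(signal, sampling_rate,
                      seizure_intervals = data.frame(start = integer(0),
                                                     end = integer(0))) {
  stopifnot(is.matrix(signal), is.numeric(sampling_rate), sampling_rate > 0)
  si <- as.data.frame(seizure_intervals)
  if (nrow(si) > 0L) {
    names(si)[1:2] <- c("start", "end")
    stopifnot(all(si$start >= 0), all(si$end <= ncol(signal)),
              all(si$end > si$start))
    if (nrow(si) > 1L) {
      stopifnot(!is.unsorted(si$start),
                all(si$start[-1L] >= si$end[-nrow(si)]))
    }
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 seizure_intervals = si),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz, %d seizure interval(s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              nrow(x$seizure_intervals)))
  invisible(x)
}

#' Seizure window starts
#'
#' Cuts each seizure interval into consecutive non-overlapping windows from
#' the interval start; an interval of length `S` yields `floor(S / W)`
#' windows.
#'
#' @param rec A [recording()].
#' @param window_size Window length in samples.
#' @return Integer vector of 0-based window start offsets.
#' @export
segment_seizures <- function(rec, window_size) {
  stopifnot(window_size >= 1L)
  starts <- integer(0)
  for (r in seq_len(nrow(rec$seizure_intervals))) {
    s <- rec$seizure_intervals$start[r]
    len <- rec$seizure_intervals$end[r] - s
    k <- len %/% window_size
    if (k > 0L) starts <- c(starts, s + window_size * (seq_len(k) - 1L))
  }
  as.integer(starts)
}

#' Class-balancing window counts for one seizure interval
#'
#' For a seizure stage of `seizure_length` samples and window size `W`:
#' `count_seizure = floor(S/W)` seizure windows, `count_prior =
#' floor(S/(2W))` non-seizure windows drawn before the interval and
#' `count_posterior = count_seizure - count_prior` after it, so the
#' non-seizure windows exactly balance the seizure windows.
#'
#' @param seizure_length Interval length in samples.
#' @param window_size Window length in samples.
#' @return Named integer vector `c(count_seizure, count_prior,
#'   count_posterior)`.
#' @export
balanced_counts <- function(seizure_length, window_size) {
  stopifnot(seizure_length >= 1L, window_size >= 1L)
  cs <- seizure_length %/% window_size
  cp <- (seizure_length %/% 2L) %/% window_size
  c(count_seizure = as.integer(cs), count_prior = as.integer(cp),
    count_posterior = as.integer(cs - cp))
}

#' Sample balanced non-seizure window starts
#'
#' For each seizure interval, draws `count_prior` windows from the non-seizure
#' region before it and `count_posterior` from the region after it, bounded by
#' the neighbouring seizure intervals (or the recording edges).  Placement is
#' uniform over valid starts with overlaps rejected, falling back to a
#' non-overlapping grid when the region is tightly packed.  Deterministic for
#' a fixed seed.
#'
#' @param rec A [recording()].
#' @param window_size Window length in samples.
#' @param seed Integer seed.
#' @return Integer vector of 0-based non-seizure window start offsets.
#' @export
sample_nonseizure_windows <- function(rec, window_size, seed = 1L) {
  stopifnot(window_size >= 1L)
  si <- rec$seizure_intervals
  n_total <- ncol(rec$signal)
  set.seed(as.integer(seed))
  out <- integer(0)
  for (r in seq_len(nrow(si))) {
    len <- si$end[r] - si$start[r]
    cnt <- balanced_counts(len, window_size)
    prior_lo <- if (r == 1L) 0L else si$end[r - 1L]
    prior_hi <- si$start[r]
    post_lo <- si$end[r]
    post_hi <- if (r == nrow(si)) n_total else si$start[r + 1L]
    out <- c(out,
             draw_region(prior_lo, prior_hi, cnt[["count_prior"]],
                         window_size, r, "prior"),
             draw_region(post_lo, post_hi, cnt[["count_posterior"]],
                         window_size, r, "posterior"))
  }
  as.integer(out)
}

# uniform placement without replacement over [lo, hi); grid fallback when
# rejection stalls (capacity is checked first)
draw_region <- function(lo, hi, count, w, interval_id, side) {
  if (count == 0L) return(integer(0))
  capacity <- (hi - lo) %/% w
  if (capacity < count)
    stop(sprintf("insufficient non-seizure room %s seizure interval %d",
                 side, interval_id))
  chosen <- integer(0)
  max_start <- hi - w
  attempts <- 0L
  while (length(chosen) < count && attempts < 200L * count) {
    cand <- lo + sample.int(max_start - lo + 1L, 1L) - 1L
    attempts <- attempts + 1L
    if (!any(abs(chosen - cand) < w)) chosen <- c(chosen, cand)
  }
  if (length(chosen) < count) {
    grid <- lo + w * (seq_len(capacity) - 1L)
    chosen <- sort(sample(grid, count))
  }
  sort(chosen)
}

#' Extract one window from a recording
#'
#' @param rec A [recording()].
#' @param start 0-based start offset.
#' @param window_size Window length in samples.
#' @return Channels x samples matrix.
#' @export
extract_window <- function(rec, start, window_size) {
  stopifnot(start >= 0L, start + window_size <= ncol(rec$signal))
  rec$signal[, (start + 1L):(start + window_size), drop = FALSE]
}

#' Balanced labelled window set for a recording
#'
#' Combines [segment_seizures()] and [sample_nonseizure_windows()] into a
#' window inventory with one non-seizure window per seizure window.
#'
#' @inheritParams sample_nonseizure_windows
#' @return A `window_set`: list with `window_size` and `entries` (data frame
#'   of `start` and `label`, label 1 = seizure, 0 = non-seizure).
#' @export
window_set <- function(rec, window_size, seed = 1L) {
  s <- segment_seizures(rec, window_size)
  ns <- sample_nonseizure_windows(rec, window_size, seed)
  entries <- data.frame(start = c(s, ns),
                        label = rep(c(1L, 0L), c(length(s), length(ns))))
  structure(list(window_size = as.integer(window_size), entries = entries),
            class = "window_set")
}
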