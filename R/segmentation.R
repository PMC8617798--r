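#' Time bounds of one segment
#'
#' Segments tile the epoch window in consecutive `bin_ms` blocks anchored
#' at the window start: segment `k` covers the half-open interval
#' `[tmin + bin_ms * (k - 1), tmin + bin_ms * k)` ms. With the study
#' window (-100..1000 ms) and 50-ms bins, segment 1 is `[-100, -50)`,
#' segment 9 is `[300, 350)`, segment 10 is `[350, 400)` and segment 22
#' (the last) is `[950, 1000)`.
#'
#' @param k Segment index, `1..kmax`.
#' @param bin_ms Bin width, ms (default 50).
#' @param epoch_window_ms Epoch window the segments tile.
#' @return Numeric length-2 vector `(start_ms, end_ms)`, half-open.
#' @export
#' @examples
#' segment_bounds(10)  # 350 400
segment_bounds <- function(k, bin_ms = 50, epoch_window_ms = c(-100, 1000)) {
  kmax <- .kmax(bin_ms, epoch_window_ms)
  if (length(k) != 1L || k != round(k) || k < 1 || k > kmax) {
    stop("segment index k must be an integer in 1..", kmax, call. = FALSE)
  }
  start <- epoch_window_ms[1] + bin_ms * (k - 1)
  c(start, start + bin_ms)
}

.kmax <- function(bin_ms, epoch_window_ms) {
  span <- diff(epoch_window_ms)
  kmax <- span / bin_ms
  if (bin_ms <= 0 || abs(kmax - round(kmax)) > 1e-9) {
    stop("epoch span (", span, " ms) is not divisible by bin_ms (", bin_ms,
         ")", call. = FALSE)
  }
  as.integer(round(kmax))
}

#' Partition a difference waveform into 50-ms segments
#'
#' Assigns each timepoint of the waveform to the segment whose half-open
#' interval contains its exact latency, so segments are disjoint and
#' jointly cover every sample. On the study grid (281 points at 256 Hz)
#' this yields 22 segments: 17 of length 13 and 5 of length 12; segments
#' 9 and 16 hold 13 channel vectors each (grid indices 77..89 and
#' 167..179).
#'
#' @param erp A [difference_erp()].
#' @param bin_ms Bin width in ms.
#' @return List of objects of class `"erp_segment"`, each with fields
#'   `k`, `bounds` (ms, half-open), `times`, and `vectors` (timepoints x
#'   channels matrix, rows in time order).
#' @export
segment_series <- function(erp, bin_ms = 50) {
  times <- erp$times
  # window start recovered from the grid: the bin edge at/below the first
  # sample, with edges anchored at multiples of bin_ms through zero
  tmin <- floor(times[1] / bin_ms + 1e-9) * bin_ms
  k_of_t <- floor((times - tmin) / bin_ms + 1e-9) + 1L
  kmax <- max(k_of_t)
  lapply(seq_len(kmax), function(k) {
    sel <- which(k_of_t == k)
    structure(
      list(k = k,
           bounds = c(tmin + bin_ms * (k - 1), tmin + bin_ms * k),
           times = times[sel],
           vectors = t(erp$data[, sel, drop = FALSE])),
      class = "erp_segment"
    )
  })
}

#' Number of channel vectors in a segment
#'
#' @param seg An `"erp_segment"`.
#' @return Integer row count of `seg$vectors` (12 or 13 on the study grid).
#' @export
segment_length <- function(seg) nrow(seg$vectors)

#' @export
print.erp_segment <- function(x, ...) {
  cat(sprintf("<erp_segment> k=%d [%g, %g) ms: %d vectors x %d channels\n",
              x$k, x$bounds[1], x$bounds[2], nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}
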