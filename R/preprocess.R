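#' Preprocessing configuration
#'
#' Parameters of the ERP preprocessing chain: band-pass filtering, PCA
#' blink correction, epoching, amplitude artifact rejection, baseline
#' correction and linear detrending.
#'
#' The band edges are half-amplitude (-6 dB) cutoffs of the zero-phase
#' filter with an asymptotic roll-off of 24 dB/octave; the amplitude
#' threshold is strict (an epoch is rejected only when some absolute value
#' exceeds it). The epoch grid holds every sample index `i` with
#' `tmin <= i * 1000 / fs < tmax` plus the onset sample, which at 256 Hz
#' and the default -100..1000 ms window gives indices -25..255, i.e.
#' 281 timepoints; the baseline covers the pre-stimulus samples
#' (indices -25..-1), excluding the onset sample.
#'
#' @param low_hz High-pass half-amplitude cutoff, Hz.
#' @param high_hz Low-pass half-amplitude cutoff, Hz.
#' @param blink_components Number of principal components removed by blink
#'   correction (0 disables it).
#' @param blink_reference_channels Channels whose mean time course
#'   identifies the blink component (default frontal pair).
#' @param reject_threshold_uv Absolute amplitude threshold in microvolts;
#'   epochs with any value strictly over it are rejected.
#' @param epoch_window_ms Length-2 vector `(tmin, tmax)` in ms around the
#'   stimulus onset, `tmin < 0 < tmax`.
#' @param baseline_window_ms Length-2 vector, ms; samples with
#'   `start <= t < end` form the baseline.
#' @param detrend Detrending mode; only `"linear"` (least-squares line per
#'   channel per epoch) is implemented.
#'
#' @return Object of class `"preprocess_config"`.
#' @export
#' @examples
#' cfg <- preprocess_config()
#' cfg$reject_threshold_uv
preprocess_config <- function(low_hz = 0.01, high_hz = 30,
                              blink_components = 1L,
                              blink_reference_channels = c("Fp1", "Fp2"),
                              reject_threshold_uv = 75,
                              epoch_window_ms = c(-100, 1000),
                              baseline_window_ms = c(-100, 0),
                              detrend = "linear") {
  stopifnot(length(epoch_window_ms) == 2L, length(baseline_window_ms) == 2L)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (reject_threshold_uv <= 0) stop("reject_threshold_uv must be positive", call. = FALSE)
  if (!(epoch_window_ms[1] < 0 && epoch_window_ms[2] > 0)) {
    stop("epoch window must straddle the stimulus onset (tmin < 0 < tmax)",
         call. = FALSE)
  }
  detrend <- match.arg(detrend, "linear")
  structure(
    list(low_hz = low_hz, high_hz = high_hz,
         blink_components = as.integer(blink_components),
         blink_reference_channels = blink_reference_channels,
         reject_threshold_uv = reject_threshold_uv,
         epoch_window_ms = epoch_window_ms,
         baseline_window_ms = baseline_window_ms,
         detrend = detrend),
    class = "preprocess_config"
  )
}

# second-order Butterworth sections for the band edges; applied with
# filtfilt, the -3 dB point of each single pass becomes the half-amplitude
# (-6 dB) point of the zero-phase result, so the configured cutoffs are
# used directly.
.band_filters <- function(cfg, fs) {
  nyq <- fs / 2
  if (cfg$high_hz >= nyq) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 cfg$high_hz, nyq), call. = FALSE)
  }
  list(
    hp = signal::butter(2, cfg$low_hz / nyq, type = "high"),
    lp = signal::butter(2, cfg$high_hz / nyq, type = "low")
  )
}

# forward-backward (zero-phase) application of one filter to the columns
# of a samples x channels matrix (compiled kernel, zero initial
# conditions on each pass)
.zero_phase <- function(flt, X) {
  .iir_filtfilt_cpp(flt$b, flt$a, X)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies second-order high-pass and low-pass Butterworth filters
#' forward and backward (zero net phase) to every channel. The cutoffs
#' are half-amplitude points of the combined response and the asymptotic
#' roll-off is 24 dB/octave on each side. Startup transients decay within
#' the recording's padding; recordings are expected to carry dead time
#' (about 30 s in the study protocol) before the first stimulus.
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()].
#' @return A filtered [recording()] of the same shape.
#' @seealso [filter_response()] for the analytic magnitude response.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  flt <- .band_filters(cfg, rec$sampling_rate)
  X <- t(rec$data)                         # samples x channels
  X <- .zero_phase(flt$hp, X)
  X <- .zero_phase(flt$lp, X)
  rec$data <- t(X)
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Analytic magnitude response of the preprocessing band-pass
#'
#' Evaluates the combined zero-phase magnitude response (the squared
#' single-pass Butterworth magnitudes) on the z-circle at the requested
#' frequencies. Used to verify the half-amplitude cutoffs and the
#' 24 dB/octave roll-off without filtering any data.
#'
#' @param cfg A [preprocess_config()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of amplitude gains in `[0, 1]`.
#' @export
#' @examples
#' filter_response(preprocess_config(), c(0.01, 10, 30), fs = 256)
filter_response <- function(cfg, freq_hz, fs = 256) {
  flt <- .band_filters(cfg, fs)
  hmag <- function(f, w) {
    k_b <- seq_along(f$b) - 1
    k_a <- seq_along(f$a) - 1
    vapply(w, function(wi) {
      num <- sum(f$b * exp(-1i * wi * k_b))
      den <- sum(f$a * exp(-1i * wi * k_a))
      Mod(num / den)
    }, 0)
  }
  w <- 2 * pi * freq_hz / fs
  (hmag(flt$hp, w) * hmag(flt$lp, w))^2   # squared: forward + backward pass
}

#' PCA-based ocular blink correction
#'
#' Decomposes the channels into principal components over time, removes
#' the `blink_components` components whose time courses correlate most
#' strongly (in absolute value) with the mean of the blink reference
#' channels (default Fp1/Fp2, where blinks dominate), and reconstructs the
#' recording from the remaining components.
#'
#' @inheritParams bandpass_filter
#' @return A corrected [recording()] of the same shape. With
#'   `blink_components = 0` the input is returned unchanged.
#' @export
correct_blinks_pca <- function(rec, cfg = preprocess_config()) {
  ncomp <- cfg$blink_components
  if (ncomp == 0L) return(rec)
  d <- nrow(rec$data)
  if (d < ncomp + 1L) {
    stop("need at least blink_components + 1 channels", call. = FALSE)
  }
  refs <- cfg$blink_reference_channels
  missing_refs <- setdiff(refs, rec$channel_labels)
  if (length(missing_refs)) {
    stop("blink reference channels absent from montage: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  X <- t(rec$data)                       # samples x channels
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  eg <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  V <- eg$vectors
  # |correlation| of each component's time course with the blink
  # reference, computed from cross-covariances (scores never formed)
  ref_ts <- rowMeans(Xc[, match(refs, rec$channel_labels), drop = FALSE])
  cross <- drop(crossprod(Xc, ref_ts)) / (nrow(Xc) - 1)   # cov(channel, ref)
  score_sd <- sqrt(pmax(eg$values, 0))
  denom <- score_sd * stats::sd(ref_ts)
  r <- abs(drop(crossprod(V, cross)) / ifelse(denom > 0, denom, Inf))
  drop_idx <- order(r, decreasing = TRUE)[seq_len(ncomp)]
  Vd <- V[, drop_idx, drop = FALSE]
  Xr <- Xc - (Xc %*% Vd) %*% t(Vd)
  Xr <- sweep(Xr, 2L, mu, "+")
  rec$data <- t(Xr)
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Epoch grid indices for a time window
#'
#' Sample indices `i` (relative to the onset sample) that make up an
#' epoch: every `i` with `tmin <= i * 1000 / fs < tmax`, and additionally
#' `i = tmax * fs / 1000` is excluded when it lands exactly on the upper
#' edge (half-open window). The study window (-100, 1000) at 256 Hz gives
#' -25..255, i.e. 281 indices; a degenerate window `(c, c)` gives the
#' single onset-aligned index.
#'
#' @param window_ms Length-2 vector `(tmin, tmax)` in ms.
#' @param fs Sampling rate, Hz.
#' @return Integer vector of grid indices.
#' @export
#' @examples
#' length(epoch_grid_indices(c(-100, 1000), 256))  # 281
epoch_grid_indices <- function(window_ms, fs) {
  .epoch_grid(window_ms, fs)
}

# epoch grid indices relative to the onset sample, in samples
.epoch_grid <- function(window_ms, fs) {
  lo <- window_ms[1] * fs / 1000
  hi <- window_ms[2] * fs / 1000
  i_min <- as.integer(ceiling(lo - 1e-9))
  i_max <- if (abs(hi - round(hi)) < 1e-9 && window_ms[2] > window_ms[1]) {
    as.integer(round(hi)) - 1L           # half-open at the top of the window
  } else {
    as.integer(floor(hi + 1e-9))
  }
  i_min:i_max
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Extracts, for each event, the samples at indices `onset + i` for grid
#' indices `i` covering the epoch window (-25..255 for the study window
#' at 256 Hz, i.e. 281 timepoints). Events too close to the recording
#' edges are dropped with a warning.
#'
#' @param rec A [recording()].
#' @param events An [event_table()].
#' @param cfg A [preprocess_config()].
#' @return Object of class `"epoch_set"` with fields `data` (trials x
#'   channels x timepoints array), `times` (ms), `categories`, and
#'   `keep_mask` (all `TRUE` initially).
#' @export
epoch_recording <- function(rec, events, cfg = preprocess_config()) {
  if (!nrow(events)) stop("cannot epoch with an empty event table", call. = FALSE)
  validate_events(events, rec)
  grid <- .epoch_grid(cfg$epoch_window_ms, rec$sampling_rate)
  n <- ncol(rec$data)
  ok <- events$onset_sample + grid[1] >= 1L &
        events$onset_sample + grid[length(grid)] <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  onsets <- events$onset_sample[ok]
  cats <- events$category[ok]
  if (!length(onsets)) stop("no events fit inside the recording", call. = FALSE)
  d <- nrow(rec$data)
  tp <- length(grid)
  data <- array(0, dim = c(length(onsets), d, tp))
  for (j in seq_along(onsets)) {
    data[j, , ] <- rec$data[, onsets[j] + grid, drop = FALSE]
  }
  structure(
    list(data = data,
         times = grid * 1000 / rec$sampling_rate,
         categories = cats,
         keep_mask = rep(TRUE, length(onsets))),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d channels x %d timepoints\n",
              dim(x$data)[1], sum(x$keep_mask), dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}

#' Amplitude-threshold artifact rejection
#'
#' Marks as rejected every epoch whose absolute amplitude strictly exceeds
#' the threshold on any channel at any timepoint ("over" the threshold: an
#' epoch peaking exactly at the threshold is kept).
#'
#' @param epochs An `"epoch_set"`.
#' @param cfg A [preprocess_config()].
#' @return The epoch set with an updated `keep_mask`.
#' @export
reject_artifacts <- function(epochs, cfg = preprocess_config()) {
  thr <- cfg$reject_threshold_uv
  peak <- apply(abs(epochs$data), 1L, max)
  epochs$keep_mask <- epochs$keep_mask & (peak <= thr)
  epochs
}

#' Baseline correction and linear detrending
#'
#' Per epoch and channel: subtract the mean over the baseline samples
#' (pre-stimulus window, onset sample excluded), then remove the
#' least-squares linear trend over the full epoch.
#'
#' @inheritParams reject_artifacts
#' @return The epoch set with corrected data.
#' @export
baseline_and_detrend <- function(epochs, cfg = preprocess_config()) {
  bw <- cfg$baseline_window_ms
  bl <- which(epochs$times >= bw[1] - 1e-9 & epochs$times < bw[2] - 1e-9)
  if (!length(bl)) stop("empty baseline window", call. = FALSE)
  dm <- dim(epochs$data)
  tp <- dm[3]
  # flatten to timepoints x (trial*channel) for vectorized fits
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = tp)
  flat <- sweep(flat, 2L, colMeans(flat[bl, , drop = FALSE]))
  tt <- seq_len(tp)
  X <- cbind(1, tt - mean(tt))
  beta <- solve(crossprod(X), crossprod(X, flat))
  flat <- flat - X %*% beta
  epochs$data <- aperm(array(flat, dim = c(tp, dm[1], dm[2])), c(2, 3, 1))
  epochs
}

#' Average kept epochs of one stimulus category
#'
#' @param epochs An `"epoch_set"` (after rejection and correction).
#' @param category `"standard"` or `"target"`.
#' @return Object of class `"erp"` with fields `data` (channels x
#'   timepoints mean waveform), `times`, `category`, `n_trials`.
#' @export
average_by_category <- function(epochs, category) {
  category <- match.arg(category, c("standard", "target"))
  sel <- which(epochs$keep_mask & epochs$categories == category)
  if (!length(sel)) {
    stop("no kept epochs of category '", category,
         "'; person unusable", call. = FALSE)
  }
  m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(data = m, times = epochs$times, category = category,
         n_trials = length(sel)),
    class = "erp"
  )
}

#' Target minus standard difference waveform from two averaged ERPs
#'
#' @param target,standard `"erp"` objects on the same grid.
#' @param person_id,gender Metadata for the resulting [difference_erp()].
#' @return A [difference_erp()].
#' @export
difference_waveform <- function(target, standard,
                                person_id = "unknown", gender = "female") {
  if (!identical(dim(target$data), dim(standard$data)) ||
      max(abs(target$times - standard$times)) > 1e-9) {
    stop("target and standard ERPs must share shape and time grid", call. = FALSE)
  }
  out <- difference_erp(target$data - standard$data, target$times,
                        person_id, gender)
  attr(out, "n_trials") <- c(target = target$n_trials,
                             standard = standard$n_trials)
  out
}

#' Full preprocessing chain for one person
#'
#' Composition, in fixed order: band-pass filter, PCA blink correction,
#' epoching, amplitude artifact rejection, baseline correction +
#' detrending, per-category averaging, difference waveform. Deterministic:
#' identical inputs and configuration give an identical result.
#'
#' @param rec A [recording()].
#' @param events An [event_table()].
#' @param cfg A [preprocess_config()].
#' @param verbose Emit per-stage messages with kept-trial counts.
#' @return A [difference_erp()] with attribute `n_trials` giving kept
#'   target/standard counts.
#' @export
preprocess_person <- function(rec, events, cfg = preprocess_config(),
                              verbose = FALSE) {
  rec <- bandpass_filter(rec, cfg)
  rec <- correct_blinks_pca(rec, cfg)
  ep <- epoch_recording(rec, events, cfg)
  ep <- reject_artifacts(ep, cfg)
  if (verbose) {
    message(sprintf("%s: kept %d/%d epochs after +/-%g uV rejection",
                    rec$person_id, sum(ep$keep_mask), length(ep$keep_mask),
                    cfg$reject_threshold_uv))
  }
  ep <- baseline_and_detrend(ep, cfg)
  tgt <- average_by_category(ep, "target")
  std <- average_by_category(ep, "standard")
  if (verbose) {
    message(sprintf("%s: averaged %d target / %d standard epochs",
                    rec$person_id, tgt$n_trials, std$n_trials))
  }
  difference_waveform(tgt, std, person_id = rec$person_id, gender = rec$gender)
}
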