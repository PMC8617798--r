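# Minimal European Data Format (EDF) reader/writer for continuous EEG.
# EDF stores 16-bit integers with a per-signal linear physical scaling;
# round trips are therefore exact only to the quantization step
# (phys range / 65535). One data record per second; the recording length
# must be a whole number of records.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

#' Write a recording as a 16-bit EDF file
#'
#' The person id and gender are stored in the patient-identification
#' header field (`"<person_id> <gender>"`). The physical range is set
#' symmetrically from the data maximum, so quantization error is at most
#' `max(abs(data)) / 32767`. The number of samples per channel must be a
#' multiple of the sampling rate (whole one-second records).
#'
#' @param rec A [recording()].
#' @param path Output `.edf` path.
#' @return Invisibly `path`.
#' @export
write_recording_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  n <- ncol(rec$data)
  if (n %% fs != 0) {
    stop("EDF writer requires whole one-second records; ",
         "pad the recording or use the matrix format", call. = FALSE)
  }
  ns <- nrow(rec$data)
  n_rec <- n %/% fs
  pmax_phys <- max(1, ceiling(max(abs(rec$data))))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))                                   # version
  wr(.edf_pad(paste(rec$person_id, rec$gender), 80))     # patient id
  wr(.edf_pad("Startdate 01-JAN-2000 X X X", 80))        # recording id
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(256L + ns * 256L, 8))                      # header bytes
  wr(.edf_pad("", 44))
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1, 8))                                     # record duration s
  wr(.edf_num(ns, 4))
  wr(paste0(vapply(rec$channel_labels, .edf_pad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80L * ns))                              # transducer
  wr(strrep(.edf_pad("uV", 8), ns))
  wr(strrep(.edf_num(-pmax_phys, 8), ns))
  wr(strrep(.edf_num(pmax_phys, 8), ns))
  wr(strrep(.edf_num(-32768L, 8), ns))
  wr(strrep(.edf_num(32767L, 8), ns))
  wr(strrep(" ", 80L * ns))                              # prefiltering
  wr(strrep(.edf_num(fs, 8), ns))
  wr(strrep(" ", 32L * ns))

  scale <- 32767 / pmax_phys
  dig <- matrix(as.integer(round(rec$data * scale)), nrow = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, idx, drop = FALSE])   # per signal contiguous
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' Requires a uniform sampling rate (identical samples-per-record across
#' signals and a constant record duration) and a consistent header;
#' contradictions raise a format error. Values are scaled to physical
#' units (microvolts) using the per-signal EDF calibration.
#'
#' @param path Input `.edf` path.
#' @return A [recording()].
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  rdn <- function(k) {
    s <- trimws(rd(k))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("malformed EDF numeric header field: '", s, "'", call. = FALSE)
    v
  }
  rd(8)                                 # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  header_bytes <- rdn(8)
  rd(44)
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  if (ns < 1L) stop("EDF header reports no signals", call. = FALSE)
  if (header_bytes != 256L + 256L * ns) {
    stop("contradictory EDF header byte count", call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80L * ns)
  rd(8L * ns)                           # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) rdn(8), 0)
  phys_max <- vapply(seq_len(ns), function(i) rdn(8), 0)
  dig_min <- vapply(seq_len(ns), function(i) rdn(8), 0)
  dig_max <- vapply(seq_len(ns), function(i) rdn(8), 0)
  rd(80L * ns)
  spr <- vapply(seq_len(ns), function(i) rdn(8), 0)
  rd(32L * ns)
  if (length(unique(spr)) != 1L) {
    stop("unsupported EDF: signals sampled at different rates", call. = FALSE)
  }
  if (rec_dur <= 0) stop("unsupported EDF: non-positive record duration", call. = FALSE)
  fs <- spr[1] / rec_dur
  if (anyDuplicated(labels)) stop("EDF file has duplicate channel labels", call. = FALSE)

  spr <- as.integer(spr[1])
  data <- matrix(0, nrow = ns, ncol = n_rec * spr)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr, size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr)    # column = signal
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    data[, idx] <- t(block)
  }
  data <- sweep(sweep(data, 1L, dig_min, "-"), 1L, gain, "*")
  data <- sweep(data, 1L, phys_min, "+")

  toks <- strsplit(patient, "\\s+")[[1]]
  gender <- if (length(toks) >= 2 && toks[2] %in% GENDERS) toks[2] else "female"
  person_id <- if (length(toks) >= 1) toks[1] else "unknown"
  recording(data, labels, fs, person_id, gender)
}
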