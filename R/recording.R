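#' Continuous multichannel EEG recording
#'
#' Container for one person's continuous EEG: a channels-by-samples matrix
#' in microvolts plus acquisition metadata. All invariants are checked at
#' construction: at least one channel, unique channel labels matching the
#' matrix rows, a positive sampling rate, and finite values.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector of unique 10/20 channel names,
#'   one per row of `data`.
#' @param sampling_rate Sampling frequency in Hz (study value 256).
#' @param person_id Opaque person identifier.
#' @param gender One of `"female"` or `"male"` (lowercase).
#'
#' @return An object of class `"recording"` with fields `data`,
#'   `channel_labels`, `sampling_rate`, `person_id`, `gender`, and derived
#'   `duration` in seconds (`samples / sampling_rate`, exact).
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 512), 2), c("Fp1", "Pz"), 256, "s01", "female")
#' rec$duration  # 2 seconds
recording <- function(data, channel_labels, sampling_rate, person_id, gender) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("recording needs at least one channel", call. = FALSE)
  if (!all(is.finite(data))) stop("recording contains non-finite values", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must equal the number of data rows", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel_labels must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  .assert_gender(gender)
  rownames(data) <- channel_labels
  structure(
    list(
      person_id = as.character(person_id),
      gender = gender,
      channel_labels = channel_labels,
      sampling_rate = sampling_rate,
      data = data,
      duration = ncol(data) / sampling_rate
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$person_id, x$gender, nrow(x$data), ncol(x$data),
              x$sampling_rate, x$duration))
  invisible(x)
}

#' Stimulus event table for an oddball run
#'
#' Events are stored as integer onset sample indices into a recording plus
#' a two-level category (`standard` frequent, `target` rare). Onsets must
#' be strictly increasing. Stimulus duration and inter-stimulus interval
#' are carried as metadata attributes.
#'
#' @param onset_sample Integer vector of onset sample indices (1-based),
#'   strictly increasing.
#' @param category Character/factor vector, each `"standard"` or `"target"`.
#' @param stim_duration_ms Stimulus duration metadata, ms (study value 150).
#' @param isi_ms Inter-stimulus interval metadata, ms (study value 1000).
#'
#' @return A data frame of class `"event_table"` with columns
#'   `onset_sample` and `category`, and attributes `stim_duration_ms`,
#'   `isi_ms`.
#' @export
#' @examples
#' ev <- event_table(c(100, 400, 700), c("standard", "target", "standard"))
#' table(ev$category)
event_table <- function(onset_sample, category,
                        stim_duration_ms = 150, isi_ms = 1000) {
  onset_sample <- as.integer(onset_sample)
  category <- as.character(category)
  if (length(onset_sample) != length(category)) {
    stop("onset_sample and category must have the same length", call. = FALSE)
  }
  if (length(onset_sample) > 1L && any(diff(onset_sample) <= 0L)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  bad <- setdiff(unique(category), c("standard", "target"))
  if (length(bad)) {
    stop("unknown event category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    onset_sample = onset_sample,
    category = factor(category, levels = c("standard", "target"))
  )
  attr(out, "stim_duration_ms") <- stim_duration_ms
  attr(out, "isi_ms") <- isi_ms
  class(out) <- c("event_table", "data.frame")
  out
}

#' Check that all events fall inside a recording
#'
#' @param events An [event_table()].
#' @param rec A [recording()].
#' @return Invisibly `events`; errors when any onset lies outside the
#'   recording's sample range.
#' @export
validate_events <- function(events, rec) {
  n <- ncol(rec$data)
  if (nrow(events) && (min(events$onset_sample) < 1L ||
                       max(events$onset_sample) > n)) {
    stop("event onsets outside recording bounds [1, ", n, "]", call. = FALSE)
  }
  invisible(events)
}

#' Read a stimulus event table from a tab-separated file
#'
#' Expects a header line with columns `onset_sample` and `category`
#' (BIDS-style events sidecar reduced to the two fields the pipeline
#' needs). An empty table is valid; downstream operations reject it.
#'
#' @param path Path to a TSV file.
#' @inheritParams event_table
#' @return An [event_table()].
#' @export
read_events <- function(path, stim_duration_ms = 150, isi_ms = 1000) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "category") %in% names(df))) {
    stop("events file must have columns onset_sample, category", call. = FALSE)
  }
  event_table(df$onset_sample, df$category,
              stim_duration_ms = stim_duration_ms, isi_ms = isi_ms)
}

#' Write a stimulus event table to a tab-separated file
#'
#' @param events An [event_table()].
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
write_events <- function(events, path) {
  utils::write.table(
    data.frame(onset_sample = events$onset_sample,
               category = as.character(events$category)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# sidecar JSON written next to matrix-format recordings / ERP matrices
.sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

.write_sidecar <- function(path, fields) {
  jsonlite::write_json(fields, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar file: ", sp, call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a continuous EEG recording
#'
#' Two interchange formats are supported: European Data Format (`"edf"`,
#' 16-bit) and a plain-text samples-by-channels TSV matrix with a one-line
#' JSON sidecar carrying `person_id`, `gender`, `sampling_rate` and
#' `channel_labels` (`"matrix"`). The format is guessed from the file
#' extension when not given. Values are returned in microvolts.
#'
#' @param path Input file path (`.edf` or `.tsv`).
#' @param format `"edf"`, `"matrix"`, or `NULL` to guess from the extension.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               edf = "edf", tsv = "matrix", txt = "matrix",
                               stop("cannot guess recording format from extension: ",
                                    path, call. = FALSE))
  switch(format,
         edf = read_recording_edf(path),
         matrix = {
           side <- .read_sidecar(path)
           m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
           recording(t(m), colnames(m),
                     sampling_rate = side$sampling_rate,
                     person_id = side$person_id, gender = side$gender)
         },
         stop("unknown recording format: ", format, call. = FALSE))
}

#' Write a continuous EEG recording
#'
#' @param rec A [recording()].
#' @param path Output path (`.edf` for EDF, `.tsv` for matrix + sidecar).
#' @param format `"edf"`, `"matrix"`, or `NULL` to guess from the extension.
#' @return Invisibly `path`.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               edf = "edf", tsv = "matrix", txt = "matrix",
                               stop("cannot guess recording format from extension: ",
                                    path, call. = FALSE))
  switch(format,
         edf = write_recording_edf(rec, path),
         matrix = {
           m <- t(rec$data)
           colnames(m) <- rec$channel_labels
           utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
           .write_sidecar(path, list(person_id = rec$person_id,
                                     gender = rec$gender,
                                     sampling_rate = rec$sampling_rate,
                                     channel_labels = rec$channel_labels))
         },
         stop("unknown recording format: ", format, call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
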