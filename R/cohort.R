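#' Target minus standard difference waveform
#'
#' The per-person averaged ERP to target stimuli minus the averaged ERP to
#' standard stimuli, a channels-by-timepoints matrix in microvolts on the
#' epoch time grid (281 points for the -100..1000 ms window at 256 Hz).
#'
#' @param data Numeric matrix, channels x timepoints, microvolts.
#' @param times Numeric vector of timepoint latencies in ms relative to
#'   stimulus onset, strictly increasing with a constant step.
#' @param person_id Person identifier.
#' @param gender `"female"` or `"male"`.
#'
#' @return Object of class `"difference_erp"`.
#' @export
difference_erp <- function(data, times, person_id, gender) {
  if (!is.matrix(data) || !all(is.finite(data))) {
    stop("difference ERP data must be a finite numeric matrix", call. = FALSE)
  }
  if (length(times) != ncol(data)) {
    stop("times length must equal the number of timepoints", call. = FALSE)
  }
  steps <- diff(times)
  if (length(steps) && (any(steps <= 0) ||
                        diff(range(steps)) > 1e-9 * max(abs(times)))) {
    stop("times must be strictly increasing with a constant step", call. = FALSE)
  }
  .assert_gender(gender)
  structure(
    list(data = data, times = as.numeric(times),
         person_id = as.character(person_id), gender = gender),
    class = "difference_erp"
  )
}

#' @export
print.difference_erp <- function(x, ...) {
  cat(sprintf("<difference_erp> %s (%s): %d channels x %d timepoints, %g..%g ms\n",
              x$person_id, x$gender, nrow(x$data), ncol(x$data),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Cohort of difference waveforms
#'
#' A list of [difference_erp()] objects, one per person, sharing channel
#' count and time grid. At least one person of each gender is required
#' (the decoder is untrainable otherwise).
#'
#' @param erps List of [difference_erp()] objects.
#' @return Object of class `"erp_cohort"`; its length is the number of
#'   persons.
#' @export
cohort_dataset <- function(erps) {
  if (!length(erps)) stop("cohort must contain at least one person", call. = FALSE)
  if (!all(vapply(erps, inherits, TRUE, "difference_erp"))) {
    stop("all cohort members must be difference_erp objects", call. = FALSE)
  }
  structure(erps, class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  g <- vapply(unclass(x), `[[`, "", "gender")
  cat(sprintf("<erp_cohort> %d persons (%d female / %d male)\n",
              length(x), sum(g == "female"), sum(g == "male")))
  invisible(x)
}

#' Genders of a cohort
#' @param cohort An [cohort_dataset()].
#' @return Factor with levels female, male, one entry per person.
#' @export
cohort_genders <- function(cohort) {
  .gender_factor(vapply(unclass(cohort), `[[`, "", "gender"))
}

#' Validate a cohort's shared grid and gender composition
#'
#' Checks that every member shares the channel count and time grid, and
#' that both genders are present. Errors on violation; otherwise returns
#' a per-person summary report.
#'
#' @param cohort An [cohort_dataset()].
#' @return Data frame with columns `person_id`, `gender`, `n_channels`,
#'   `n_timepoints`, invisibly printed gender counts as attributes.
#' @export
validate_cohort <- function(cohort) {
  erps <- unclass(cohort)
  d <- vapply(erps, function(e) nrow(e$data), 0L)
  tp <- vapply(erps, function(e) ncol(e$data), 0L)
  if (length(unique(d)) != 1L || length(unique(tp)) != 1L) {
    stop("cohort grid mismatch: channel/timepoint counts differ across persons",
         call. = FALSE)
  }
  t0 <- erps[[1]]$times
  for (e in erps[-1]) {
    if (max(abs(e$times - t0)) > 1e-9) {
      stop("cohort grid mismatch: time grids differ across persons", call. = FALSE)
    }
  }
  g <- cohort_genders(cohort)
  if (any(table(g) == 0L)) {
    stop("cohort contains a single gender only; decoder is untrainable",
         call. = FALSE)
  }
  report <- data.frame(
    person_id = vapply(erps, `[[`, "", "person_id"),
    gender = as.character(g),
    n_channels = d,
    n_timepoints = tp
  )
  attr(report, "gender_counts") <- table(g)
  report
}

#' Write a difference waveform as TSV matrix + JSON sidecar
#'
#' The matrix is written timepoints-by-channels with channel labels as the
#' header; `times`, `person_id` and `gender` go to the sidecar.
#'
#' @param erp A [difference_erp()].
#' @param path Output `.tsv` path.
#' @return Invisibly `path`.
#' @export
write_difference_erp <- function(erp, path) {
  m <- t(erp$data)
  colnames(m) <- rownames(erp$data) %||% paste0("ch", seq_len(nrow(erp$data)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_sidecar(path, list(person_id = erp$person_id, gender = erp$gender,
                            times_ms = erp$times))
  invisible(path)
}

#' Read a difference waveform written by [write_difference_erp()]
#' @param path Input `.tsv` path.
#' @return A [difference_erp()].
#' @export
read_difference_erp <- function(path) {
  side <- .read_sidecar(path)
  m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
  d <- t(m)
  rownames(d) <- colnames(m)
  difference_erp(d, side$times_ms, side$person_id, side$gender)
}

#' Write a whole cohort to a directory
#' @param cohort An [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unclass(cohort), function(e) {
    p <- file.path(dir, paste0(e$person_id, "_diff.tsv"))
    write_difference_erp(e, p)
    p
  }, "")
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `*_diff.tsv` files.
#' @return An [cohort_dataset()].
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "_diff\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no *_diff.tsv files in ", dir, call. = FALSE)
  cohort_dataset(lapply(files, read_difference_erp))
}
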