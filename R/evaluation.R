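#' Evaluation configuration
#'
#' Parameters of the leave-one-out decoding experiment: the classifier
#' battery, segment bin width, chance level for a binary problem,
#' the physiologically meaningful latency window, display rounding, and
#' the Wilcoxon/Bonferroni settings.
#'
#' @param classifiers Named list of [classifier_spec()] objects.
#' @param bin_ms Segment width, ms.
#' @param chance_level Chance accuracy for the binary problem.
#' @param meaningful_window_ms Latency window (ms) in which decoding is
#'   physiologically interpretable; visual information reaches cortex
#'   after ~100 ms and the P3 resolves by ~750-800 ms.
#' @param rounding Decimals used for displayed rates (selection always
#'   uses unrounded values).
#' @param wilcoxon_mu Null location for the signed-rank test.
#' @param bonferroni_m Family size for Bonferroni correction (default 8:
#'   4 classifiers x 2 examined segments).
#' @param detail_segments Segments for which per-person rate tables are
#'   reported by [run_experiment()].
#' @param seed Integer seed for stochastic classifiers.
#' @return Object of class `"evaluation_config"`.
#' @export
evaluation_config <- function(classifiers = default_classifiers(),
                              bin_ms = 50, chance_level = 0.5,
                              meaningful_window_ms = c(100, 800),
                              rounding = 2L, wilcoxon_mu = 0.5,
                              bonferroni_m = 8L,
                              detail_segments = c(9L, 16L),
                              seed = 1L) {
  if (!(chance_level > 0 && chance_level < 1)) {
    stop("chance_level must lie in (0, 1)", call. = FALSE)
  }
  if (bonferroni_m < 1L) stop("bonferroni_m must be >= 1", call. = FALSE)
  if (is.null(names(classifiers)) || any(names(classifiers) == "")) {
    names(classifiers) <- vapply(classifiers, `[[`, "", "kind")
  }
  structure(
    list(classifiers = classifiers, bin_ms = bin_ms,
         chance_level = chance_level,
         meaningful_window_ms = meaningful_window_ms,
         rounding = as.integer(rounding), wilcoxon_mu = wilcoxon_mu,
         bonferroni_m = as.integer(bonferroni_m),
         detail_segments = as.integer(detail_segments),
         seed = as.integer(seed)),
    class = "evaluation_config"
  )
}

#' Leave-one-out evaluation of one segment and classifier
#'
#' For every person in the cohort: train the bottom classifier on the
#' segment-k vectors of the remaining persons, classify the held-out
#' person's vectors, and score (a) the fraction of vectors assigned the
#' true gender (the per-person rate) and (b) whether the majority vote
#' over the segment recovers the true gender. The segment accuracy is the
#' mean of the per-person rates; vote-level accuracy is returned as a
#' secondary summary.
#'
#' @param cohort An [cohort_dataset()].
#' @param spec A [classifier_spec()].
#' @param k Segment index.
#' @param bin_ms Segment width, ms.
#' @param seed Seed for stochastic classifiers (applied per fit, offset by
#'   the person index, so each LOO fold is independently reproducible).
#' @return List with `rates` (named per-person vector), `accuracy`
#'   (their mean), `votes` (per-person predicted gender), and
#'   `vote_accuracy`.
#' @export
loo_segment_eval <- function(cohort, spec, k, bin_ms = 50, seed = 1L) {
  erps <- unclass(cohort)
  ids <- vapply(erps, `[[`, "", "person_id")
  truth <- vapply(erps, `[[`, "", "gender")
  # segment every person once; folds reuse the stacked matrix
  # (row order: person order, then time order, as in build_training_matrix)
  segs <- lapply(erps, function(e) segment_series(e, bin_ms)[[k]]$vectors)
  X <- do.call(rbind, segs)
  owner <- rep(seq_along(erps), vapply(segs, nrow, 0L))
  y <- .gender_factor(rep(truth, vapply(segs, nrow, 0L)))
  rates <- numeric(length(erps))
  votes <- character(length(erps))
  for (p in seq_along(erps)) {
    keep <- owner != p
    if (any(table(y[keep]) == 0L)) {
      stop("training matrix has a single class; cannot train", call. = FALSE)
    }
    model <- train_classifier(spec, X[keep, , drop = FALSE], y[keep],
                              seed = if (is.null(seed)) NULL else seed + p)
    labels <- classify_vectors(model, X[!keep, , drop = FALSE])
    rates[p] <- person_rate(labels, truth[p])
    votes[p] <- suppressMessages(
      vote_gender(vote_rates(labels), tie_break = model$majority_gender))
  }
  names(rates) <- ids
  names(votes) <- ids
  list(rates = rates, accuracy = mean(rates), votes = votes,
       vote_accuracy = mean(votes == truth))
}

#' Segment-by-classifier accuracy table
#'
#' Runs [loo_segment_eval()] for every segment and every classifier in
#' the configuration. The `accuracy` matrix is the per-segment mean of
#' per-person rates (unrounded; a rounded copy for display is in
#' `accuracy_rounded`).
#'
#' @param cohort An [cohort_dataset()].
#' @param cfg An [evaluation_config()].
#' @return Object of class `"segment_accuracy_table"` with fields
#'   `accuracy` (kmax x classifiers matrix), `accuracy_rounded`,
#'   `vote_accuracy`, `per_person` (kmax x classifiers x persons array),
#'   and `bounds` (kmax x 2 matrix of segment edges, ms).
#' @export
accuracy_table <- function(cohort, cfg = evaluation_config()) {
  validate_cohort(cohort)
  erps <- unclass(cohort)
  segs <- segment_series(erps[[1]], cfg$bin_ms)
  kmax <- length(segs)
  cls <- names(cfg$classifiers)
  ids <- vapply(erps, `[[`, "", "person_id")
  acc <- matrix(NA_real_, kmax, length(cls), dimnames = list(NULL, cls))
  vacc <- acc
  per <- array(NA_real_, dim = c(kmax, length(cls), length(erps)),
               dimnames = list(NULL, cls, ids))
  for (k in seq_len(kmax)) {
    for (cl in cls) {
      res <- loo_segment_eval(cohort, cfg$classifiers[[cl]], k,
                              bin_ms = cfg$bin_ms, seed = cfg$seed)
      acc[k, cl] <- res$accuracy
      vacc[k, cl] <- res$vote_accuracy
      per[k, cl, ] <- res$rates
    }
  }
  structure(
    list(accuracy = acc,
         accuracy_rounded = round(acc, cfg$rounding),
         vote_accuracy = vacc,
         per_person = per,
         bounds = t(vapply(segs, `[[`, c(0, 0), "bounds"))),
    class = "segment_accuracy_table"
  )
}

#' @export
print.segment_accuracy_table <- function(x, ...) {
  cat("<segment_accuracy_table>\n")
  df <- data.frame(k = seq_len(nrow(x$accuracy)),
                   window = sprintf("[%g, %g)", x$bounds[, 1], x$bounds[, 2]),
                   x$accuracy_rounded, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Best-scoring segment(s) of one classifier
#'
#' All segment indices attaining the maximal accuracy (a set, since ties
#' occur). Selection uses unrounded values.
#'
#' @param accuracy_column Numeric vector of per-segment accuracies.
#' @return Integer vector of segment indices.
#' @export
#' @examples
#' best_segment(c(0.5, 0.8, 0.8, 0.3))  # 2 3
best_segment <- function(accuracy_column) {
  if (!length(accuracy_column)) stop("empty accuracy column", call. = FALSE)
  which(accuracy_column == max(accuracy_column))
}

#' Proportion of persons decoded above chance
#'
#' @param rates Per-person rates.
#' @param chance Chance level; the comparison is strict (`>`).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_above_chance <- function(rates, chance = 0.5) {
  if (!length(rates)) stop("empty rates vector", call. = FALSE)
  mean(rates > chance)
}

#' Count above-chance segments inside a latency window
#'
#' Counts segments whose interval lies fully inside the window and whose
#' accuracy is strictly above chance. The window must align with segment
#' edges. The study window 100-800 ms covers segments 5..18 (14 of 22).
#'
#' @param accuracy_column Per-segment accuracies (length kmax).
#' @param window_ms Length-2 latency window, ms.
#' @param bin_ms,epoch_window_ms Segment grid parameters.
#' @param chance Chance level, strict comparison.
#' @return Integer count.
#' @export
count_segments_above_chance <- function(accuracy_column,
                                        window_ms = c(100, 800),
                                        bin_ms = 50,
                                        epoch_window_ms = c(-100, 1000),
                                        chance = 0.5) {
  kmax <- .kmax(bin_ms, epoch_window_ms)
  if (length(accuracy_column) != kmax) {
    stop("accuracy column length (", length(accuracy_column),
         ") does not match kmax (", kmax, ")", call. = FALSE)
  }
  if (any(abs((window_ms - epoch_window_ms[1]) %% bin_ms) > 1e-9)) {
    stop("window is not aligned to segment boundaries", call. = FALSE)
  }
  bounds <- t(vapply(seq_len(kmax), segment_bounds, c(0, 0),
                     bin_ms = bin_ms, epoch_window_ms = epoch_window_ms))
  inside <- bounds[, 1] >= window_ms[1] - 1e-9 & bounds[, 2] <= window_ms[2] + 1e-9
  sum(accuracy_column[inside] > chance)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests whether per-person rates exceed the chance level (one-sided,
#' `greater`). Zero differences are dropped; ties receive average ranks;
#' the exact null distribution is used when possible and the
#' tie-corrected normal approximation otherwise (the behaviour of
#' [stats::wilcox.test()]). The p-value is Bonferroni-corrected by the
#' family size `m`. When every rate equals the null location the test is
#' degenerate: `V` is `NA` and `p = 1`.
#'
#' @param rates Per-person rates.
#' @param mu Null location (chance level).
#' @param m Bonferroni family size.
#' @return List with `V` (signed-rank statistic), `p` (raw), `p_corrected`
#'   (`min(1, m * p)`), `n_nonzero` (rates differing from `mu`).
#' @export
wilcoxon_vs_chance <- function(rates, mu = 0.5, m = 1L) {
  if (!length(rates)) stop("empty rates vector", call. = FALSE)
  if (m < 1L) stop("bonferroni family size m must be >= 1", call. = FALSE)
  nonzero <- sum(rates != mu)
  if (nonzero == 0L) {
    return(list(V = NA_real_, p = 1, p_corrected = 1, n_nonzero = 0L))
  }
  w <- suppressWarnings(
    stats::wilcox.test(rates, mu = mu, alternative = "greater"))
  list(V = unname(w$statistic), p = w$p.value,
       p_corrected = min(1, m * w$p.value), n_nonzero = nonzero)
}

#' Run the full decoding experiment on a cohort
#'
#' Computes the segment-by-classifier accuracy table, per-person rate
#' tables for the configured detail segments, best segments per
#' classifier, proportions of above-chance persons, above-chance segment
#' counts inside the meaningful window, and Wilcoxon tests vs chance for
#' the detail segments. Tabular values are rounded for display per the
#' configuration; all selections use unrounded values.
#'
#' @param cohort An [cohort_dataset()].
#' @param cfg An [evaluation_config()].
#' @return Object of class `"decoding_report"`: a list with elements
#'   `table` ([accuracy_table()] result), `rate_tables`, `best_segments`,
#'   `proportions_above_chance`, `segments_above_chance`, `wilcoxon`, and
#'   `config`.
#' @export
run_experiment <- function(cohort, cfg = evaluation_config()) {
  tab <- accuracy_table(cohort, cfg)
  cls <- colnames(tab$accuracy)
  epoch_window <- c(tab$bounds[1, 1], tab$bounds[nrow(tab$bounds), 2])

  rate_tables <- lapply(cfg$detail_segments, function(k) {
    m <- t(tab$per_person[k, , , drop = TRUE])
    round(m, cfg$rounding)
  })
  names(rate_tables) <- paste0("segment_", cfg$detail_segments)

  best <- lapply(cls, function(cl) best_segment(tab$accuracy[, cl]))
  names(best) <- cls

  props <- lapply(cfg$detail_segments, function(k) {
    vapply(cls, function(cl)
      proportion_above_chance(tab$per_person[k, cl, ], cfg$chance_level), 0)
  })
  names(props) <- paste0("segment_", cfg$detail_segments)

  counts <- vapply(cls, function(cl) {
    count_segments_above_chance(tab$accuracy[, cl],
                                window_ms = cfg$meaningful_window_ms,
                                bin_ms = cfg$bin_ms,
                                epoch_window_ms = epoch_window,
                                chance = cfg$chance_level)
  }, 0L)

  wil <- lapply(cfg$detail_segments, function(k) {
    lapply(cls, function(cl) {
      wilcoxon_vs_chance(tab$per_person[k, cl, ],
                         mu = cfg$wilcoxon_mu, m = cfg$bonferroni_m)
    }) -> res
    names(res) <- cls
    res
  })
  names(wil) <- paste0("segment_", cfg$detail_segments)

  structure(
    list(table = tab, rate_tables = rate_tables, best_segments = best,
         proportions_above_chance = props, segments_above_chance = counts,
         wilcoxon = wil, config = cfg),
    class = "decoding_report"
  )
}

#' @export
print.decoding_report <- function(x, ...) {
  print(x$table)
  cat("\nBest segments: ",
      paste(sprintf("%s={%s}", names(x$best_segments),
                    vapply(x$best_segments, paste, "", collapse = ",")),
            collapse = "  "), "\n")
  cat("Above-chance segments in [",
      paste(x$config$meaningful_window_ms, collapse = ", "), "] ms: ",
      paste(sprintf("%s=%d", names(x$segments_above_chance),
                    x$segments_above_chance), collapse = "  "), "\n")
  invisible(x)
}

#' Write a decoding report to a directory
#'
#' Emits TSV tables (segment accuracies, per-person rates) and a JSON
#' summary (best segments, proportions, counts, Wilcoxon results).
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly the vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tab <- report$table
  acc <- data.frame(k = seq_len(nrow(tab$accuracy)),
                    start_ms = tab$bounds[, 1], end_ms = tab$bounds[, 2],
                    tab$accuracy_rounded, check.names = FALSE)
  f <- file.path(dir, "segment_accuracy.tsv")
  utils::write.table(acc, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  for (nm in names(report$rate_tables)) {
    f <- file.path(dir, paste0("rates_", nm, ".tsv"))
    m <- report$rate_tables[[nm]]
    utils::write.table(data.frame(person = rownames(m), m, check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(best_segments = report$best_segments,
         proportions_above_chance = report$proportions_above_chance,
         segments_above_chance = as.list(report$segments_above_chance),
         wilcoxon = report$wilcoxon),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
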