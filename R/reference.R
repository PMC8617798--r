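#' Published reference results bundled for consistency checking
#'
#' The package ships, as plain-text data, the summary tables reported by
#' the original oddball gender-decoding study this pipeline re-implements:
#' the per-segment leave-one-out accuracies of the four classifiers
#' (22 segments x 4 classifiers, two-decimal values) and the per-person
#' rates for the two highlighted segments (300-350 ms and 650-700 ms;
#' 20 persons x 4 classifiers each). They let the aggregation layer be
#' validated against printed results without any raw data: feeding the
#' per-person columns through the mean statistic must reproduce the
#' per-segment table's highlighted cells, and the proportion/count
#' summaries must reproduce the reported values.
#'
#' @return List with elements `segment_accuracy` (data frame: `k`,
#'   `start_ms`, `end_ms`, `knn`, `nb`, `rf`, `svm`),
#'   `rates_segment9` and `rates_segment16` (data frames: `person` plus
#'   one column per classifier).
#' @export
#' @examples
#' ref <- reference_study_tables()
#' round(mean(ref$rates_segment16$rf), 2)  # 0.85
reference_study_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "erpdecode",
                                  mustWork = TRUE)
  list(
    segment_accuracy = utils::read.delim(path("reference_segment_accuracy.tsv")),
    rates_segment9 = utils::read.delim(path("reference_rates_segment9.tsv")),
    rates_segment16 = utils::read.delim(path("reference_rates_segment16.tsv"))
  )
}
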