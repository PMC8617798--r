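#' Bottom-level classifier specification
#'
#' The per-vector classifier applied to the channel vector at every
#' timepoint of a segment. Four families are supported, matching common
#' practice in ERP decoding: `knn` (3 nearest neighbours, Euclidean
#' metric), `gnb` (Gaussian naive Bayes), `rf` (random forest, 100 trees,
#' feature subsets of size `floor(sqrt(d))`), and `svm` (polynomial-kernel
#' support vector machine, degree 3, unit cost). No feature scaling is
#' applied by default: all features share units (microvolts).
#'
#' @param kind One of `"knn"`, `"gnb"`, `"rf"`, `"svm"`.
#' @param ... Hyperparameter overrides for the kind: `k` (knn);
#'   `n_trees` (rf); `degree`, `cost` (svm); `scale` (svm, logical).
#' @return Object of class `"classifier_spec"`.
#' @export
#' @examples
#' classifier_spec("knn")$hyper$k  # 3
classifier_spec <- function(kind = c("knn", "gnb", "rf", "svm"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 3L),
    gnb = list(),
    rf  = list(n_trees = 100L),
    svm = list(degree = 3L, cost = 1, scale = FALSE)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hyper <- utils::modifyList(defaults, over)
  if (kind == "rf" && hyper$n_trees < 1L) {
    stop("random forest needs at least one tree", call. = FALSE)
  }
  if (kind == "knn" && hyper$k < 1L) stop("knn needs k >= 1", call. = FALSE)
  structure(list(kind = kind, hyper = hyper), class = "classifier_spec")
}

#' Default classifier battery
#'
#' The four bottom-level classifiers compared by the pipeline, in fixed
#' order: 3-NN, Gaussian naive Bayes, random forest, polynomial SVM.
#'
#' @return Named list of [classifier_spec()] objects
#'   (`knn`, `gnb`, `rf`, `svm`).
#' @export
default_classifiers <- function() {
  list(knn = classifier_spec("knn"), gnb = classifier_spec("gnb"),
       rf = classifier_spec("rf"), svm = classifier_spec("svm"))
}

#' Train a bottom-level classifier
#'
#' Fits the specified model to a vectors-by-features training matrix with
#' binary gender labels. Stochastic models (random forest) are seeded
#' explicitly for reproducibility; `knn` stores the training set (lazy).
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric matrix, training vectors x features (channels).
#' @param y Labels, coerced to a factor with levels female, male; both
#'   levels must be present.
#' @param seed Optional integer seed applied before fitting stochastic
#'   models.
#' @return Object of class `"trained_model"` predicting a gender for any
#'   d-vector; carries the training dimensionality and the training-set
#'   majority gender (used for vote tie-breaks).
#' @export
train_classifier <- function(spec, x, y, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- .gender_factor(as.character(y))
  if (any(table(y) == 0L)) {
    stop("training labels contain a single class only", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  h <- spec$hyper
  fit <- switch(spec$kind,
    knn = list(train = x, cl = y),
    gnb = e1071::naiveBayes(x, y),
    rf  = randomForest::randomForest(
            x, y, ntree = h$n_trees, mtry = max(1L, floor(sqrt(ncol(x))))),
    svm = e1071::svm(x, y, kernel = "polynomial", degree = h$degree,
                     cost = h$cost, scale = h$scale)
  )
  tab <- table(y)
  majority <- names(tab)[which.max(tab)]   # ties resolve to first level
  structure(
    list(spec = spec, fit = fit, d = ncol(x), majority_gender = majority),
    class = "trained_model"
  )
}

#' Classify every channel vector of a segment
#'
#' Applies the trained bottom-level model to each row of the segment's
#' vectors matrix, yielding one gender label per timepoint.
#'
#' @param model A [train_classifier()] result.
#' @param seg An `"erp_segment"` (or a plain vectors x channels matrix).
#' @return Factor of predicted genders, one per vector.
#' @export
classify_vectors <- function(model, seg) {
  newx <- if (inherits(seg, "erp_segment")) seg$vectors else as.matrix(seg)
  if (ncol(newx) != model$d) {
    stop("dimensionality mismatch: model trained on d=", model$d,
         ", segment has d=", ncol(newx), call. = FALSE)
  }
  out <- switch(model$spec$kind,
    knn = class::knn(model$fit$train, newx, model$fit$cl,
                     k = model$spec$hyper$k),
    gnb = stats::predict(model$fit, newx),
    rf  = stats::predict(model$fit, newx),
    svm = stats::predict(model$fit, newx)
  )
  .gender_factor(as.character(out))
}

#' Per-gender vote rates over a segment's labels
#'
#' For each gender, the fraction of the segment's timepoint vectors the
#' bottom classifier assigned to it. The two rates always sum to one
#' (every vector receives a label).
#'
#' @param labels Factor/character vector of per-vector predicted genders.
#' @return Named numeric vector `c(female = ..., male = ...)`.
#' @export
#' @examples
#' vote_rates(rep(c("female", "male"), c(7, 6)))  # 7/13, 6/13
vote_rates <- function(labels) {
  labels <- .gender_factor(as.character(labels))
  if (!length(labels) || anyNA(labels)) {
    stop("labels must be a nonempty sequence of gender labels", call. = FALSE)
  }
  tab <- table(labels)
  as.numeric(tab) / length(labels) -> r
  names(r) <- names(tab)
  r
}

#' Majority-vote segment decision
#'
#' Picks the gender with the larger vote rate. Ties (possible only for
#' even segment lengths) are broken toward the training-set majority
#' gender and reported with a message.
#'
#' @param rates Named rates from [vote_rates()].
#' @param tie_break Gender to prefer on an exact tie (pass the trained
#'   model's `majority_gender`).
#' @return A single gender label.
#' @export
vote_gender <- function(rates, tie_break = GENDERS[1]) {
  stopifnot(all(GENDERS %in% names(rates)))
  if (rates["female"] == rates["male"]) {
    message("vote tie (0.5/0.5); broken toward training majority '",
            tie_break, "'")
    return(tie_break)
  }
  names(rates)[which.max(rates)]
}

#' Fraction of a segment's vectors assigned to the true gender
#'
#' The per-person, per-segment classification rate: the vote rate of the
#' person's true gender. Always a multiple of `1 / segment length` and
#' invariant to the order of the labels.
#'
#' @param labels Per-vector predicted genders.
#' @param true_gender The person's gender.
#' @return Rate in `[0, 1]`.
#' @export
person_rate <- function(labels, true_gender) {
  .assert_gender(true_gender)
  unname(vote_rates(labels)[true_gender])
}

#' Stack segment-k vectors of all training persons into one matrix
#'
#' The bottom-level training set for leave-one-out evaluation: every
#' timepoint vector of segment `k` from every person except the excluded
#' one, labeled with the owning person's gender. Row order is
#' deterministic (cohort order, then time order). With a 20-person cohort
#' and a 13-sample segment this yields a 247 x d matrix.
#'
#' @param cohort An [cohort_dataset()].
#' @param k Segment index.
#' @param exclude `person_id` of the held-out person (or `NULL` for none).
#' @param bin_ms Segment bin width, ms.
#' @return List with `x` (matrix) and `y` (gender factor).
#' @export
build_training_matrix <- function(cohort, k, exclude = NULL, bin_ms = 50) {
  erps <- unclass(cohort)
  ids <- vapply(erps, `[[`, "", "person_id")
  if (!is.null(exclude)) {
    if (!exclude %in% ids) stop("excluded person not in cohort", call. = FALSE)
    erps <- erps[ids != exclude]
  }
  parts <- lapply(erps, function(e) {
    seg <- segment_series(e, bin_ms)[[k]]
    list(x = seg$vectors, y = rep(e$gender, nrow(seg$vectors)))
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  y <- .gender_factor(unlist(lapply(parts, `[[`, "y")))
  if (any(table(y) == 0L)) {
    stop("training matrix has a single class; cannot train", call. = FALSE)
  }
  list(x = x, y = y)
}
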