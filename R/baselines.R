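#' Majority-vote fusion baseline
#'
#' Each predictor casts one vote for its argmax location; abstaining
#' predictors (all-zero score vectors) cast no vote. The plurality
#' location wins; ties, and the all-abstain case, fall back to
#' canonical vocabulary order, matching the consensus tie-break.
#'
#' @param matrix A [score_matrix()].
#' @return Character vector of predicted locations, one per sequence.
#' @export
majority_vote <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (n_predictors(matrix) < 1) stop("no predictors", call. = FALSE)
  locs <- matrix$vocabulary$locations
  m <- length(locs)
  counts <- base::matrix(0, n_sequences(matrix), m)
  for (block in matrix$scores) {
    voting <- rowSums(block) > 0
    pick <- max.col(block, ties.method = "first")
    idx <- cbind(which(voting), pick[voting])
    counts[idx] <- counts[idx] + 1
  }
  decide_location(counts, matrix$vocabulary)
}

#' Average-probability-vote fusion baseline
#'
#' Argmax of the unweighted mean of the predictors' normalized score
#' vectors; identical, sequence by sequence, to the weighted consensus
#' with all weights equal, and shares its canonical-order tie-break.
#'
#' @param matrix A [score_matrix()].
#' @return Character vector of predicted locations, one per sequence.
#' @export
average_probability_vote <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (n_predictors(matrix) < 1) stop("no predictors", call. = FALSE)
  mean_scores <- Reduce(`+`, matrix$scores) / n_predictors(matrix)
  decide_location(mean_scores, matrix$vocabulary)
}

#' Per-class and overall accuracy report
#'
#' @param predictions,labels Character vectors of canonical locations.
#' @param vocabulary A [location_vocabulary()].
#' @param method_name Label for the row.
#' @return An object of class `accuracy_report`: `method_name`,
#'   `per_class` (named vector; `NA` for classes with no sequences),
#'   `overall`, `n_sequences`.
#' @export
accuracy_report <- function(predictions, labels, vocabulary,
                            method_name = "method") {
  stopifnot(inherits(vocabulary, "location_vocabulary"))
  per_class <- vapply(vocabulary$locations, function(loc) {
    in_class <- labels == loc
    if (!any(in_class)) return(NA_real_)
    mean(predictions[in_class] == loc)
  }, numeric(1))
  structure(list(method_name = method_name, per_class = per_class,
                 overall = accuracy(predictions, labels),
                 n_sequences = length(labels)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$method_name, ": overall ",
      format(x$overall, digits = 4), " on ", x$n_sequences,
      " sequences\n", sep = "")
  print(round(x$per_class, 4))
  invisible(x)
}

# standalone argmax predictions of one predictor block
.standalone_predictions <- function(matrix, predictor) {
  decide_location(matrix$scores[[predictor]], matrix$vocabulary)
}

#' Standalone accuracy of every base predictor
#'
#' One accuracy report per predictor, using its own argmax
#' predictions — the per-tool accuracy table a committee is assessed
#' by before fusion. Fusion baselines can be appended for a side-by-side
#' comparison.
#'
#' @param matrix A labeled [score_matrix()].
#' @param include_fusion Also append `majority_vote` and
#'   `average_probability_vote` rows (default `FALSE`).
#' @return A list of [accuracy_report()] objects, one per method.
#' @export
per_predictor_report <- function(matrix, include_fusion = FALSE) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (is.null(matrix$labels)) {
    stop("per-predictor accuracy requires a labeled matrix", call. = FALSE)
  }
  reports <- lapply(predictor_names(matrix), function(p) {
    accuracy_report(.standalone_predictions(matrix, p), matrix$labels,
                    matrix$vocabulary, method_name = p)
  })
  names(reports) <- predictor_names(matrix)
  if (include_fusion) {
    reports$majority_vote <- accuracy_report(
      majority_vote(matrix), matrix$labels, matrix$vocabulary,
      "majority_vote")
    reports$average_probability_vote <- accuracy_report(
      average_probability_vote(matrix), matrix$labels, matrix$vocabulary,
      "average_probability_vote")
  }
  reports
}

#' Tabulate accuracy reports
#'
#' @param reports A list of [accuracy_report()] objects.
#' @return A data frame with one row per method and one column per
#'   location plus `overall` and `n_sequences`.
#' @export
report_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(r) {
    c(as.list(r$per_class), overall = r$overall,
      n_sequences = r$n_sequences)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df <- cbind(method = vapply(reports, `[[`, "", "method_name"), df)
  rownames(df) <- NULL
  df
}
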