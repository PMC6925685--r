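#' Committee ablation cases
#'
#' The robustness protocol reduces the predictor committee by
#' accuracy-based rules and refits the consensus on each reduced
#' committee: remove the single best tool (`drop_best`), keep only
#' tools at or above a threshold (`keep_ge_threshold`), or keep only
#' tools below it (`keep_lt_threshold`).
#'
#' @param rule One of `"drop_best"`, `"keep_ge_threshold"`,
#'   `"keep_lt_threshold"`.
#' @param threshold Accuracy threshold in `[0, 1]`; required for the
#'   threshold rules.
#' @param case_id Optional identifier (defaults to a descriptive one).
#' @return An object of class `ablation_case`.
#' @export
ablation_case <- function(rule = c("drop_best", "keep_ge_threshold",
                                   "keep_lt_threshold"),
                          threshold = NULL, case_id = NULL) {
  rule <- match.arg(rule)
  if (rule == "drop_best") {
    if (!is.null(threshold)) stop("drop_best takes no threshold", call. = FALSE)
  } else {
    if (is.null(threshold) || threshold < 0 || threshold > 1) {
      stop(rule, " requires a threshold in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(case_id)) {
    case_id <- if (rule == "drop_best") "drop_best" else
      paste0(sub("_threshold", "", rule), "_", format(threshold))
  }
  structure(list(case_id = case_id, rule = rule, threshold = threshold),
            class = "ablation_case")
}

#' The nine canonical ablation cases
#'
#' Drop the single best predictor, then keep-at-or-above / keep-below
#' pairs at thresholds 0.9, 0.8, 0.7 and 0.6.
#'
#' @return A named list of [ablation_case()] objects.
#' @export
canonical_ablation_cases <- function() {
  cases <- c(list(ablation_case("drop_best")),
             unlist(lapply(c(0.9, 0.8, 0.7, 0.6), function(t) {
               list(ablation_case("keep_ge_threshold", t),
                    ablation_case("keep_lt_threshold", t))
             }), recursive = FALSE))
  names(cases) <- vapply(cases, `[[`, "", "case_id")
  cases
}

#' Select a reduced committee under an ablation rule
#'
#' @param reports A list of [accuracy_report()] objects, one per
#'   predictor (overall accuracy defined), in committee order.
#' @param case An [ablation_case()].
#' @return Character vector of surviving predictor names; may be empty
#'   (an untestable case).
#' @export
select_committee <- function(reports, case) {
  stopifnot(inherits(case, "ablation_case"))
  overall <- vapply(reports, `[[`, numeric(1), "overall")
  nms <- vapply(reports, `[[`, "", "method_name")
  if (anyNA(overall)) stop("overall accuracy undefined for some predictor",
                           call. = FALSE)
  keep <- switch(case$rule,
    drop_best = nms[-which.max(overall)],  # ties: first in input order drops
    keep_ge_threshold = nms[overall >= case$threshold],
    keep_lt_threshold = nms[overall < case$threshold])
  keep
}

#' Run the ablation grid
#'
#' For each case the committee is reduced (by default on test-set
#' per-predictor accuracy, matching the protocol the case thresholds
#' refer to; note this leaks test information into committee selection
#' — a `select_on = "train"` mode avoids that), weights are
#' re-optimized on the reduced training committee, and per-class plus
#' overall accuracy is evaluated on the reduced test committee. Cases
#' whose committee is empty are untestable and reported as `NA`.
#'
#' @param train,test Labeled [score_matrix()] objects sharing the same
#'   vocabulary and predictor set.
#' @param cases List of [ablation_case()] objects (defaults to the
#'   nine canonical cases).
#' @param config A [swarm_config()]; its seed drives every refit.
#' @param weights_per Passed to [fit_consensus()].
#' @param select_on `"test"` (default) or `"train"`: which split's
#'   per-predictor accuracy drives committee selection.
#' @return A data frame with one row per case: `case_id`, `committee`
#'   (comma-separated survivors), `n_predictors`, one column per
#'   location, `overall`, and `train_fitness`.
#' @export
run_ablation_grid <- function(train, test,
                              cases = canonical_ablation_cases(),
                              config = swarm_config(),
                              weights_per = c("class", "predictor"),
                              select_on = c("test", "train")) {
  weights_per <- match.arg(weights_per)
  select_on <- match.arg(select_on)
  stopifnot(inherits(train, "score_matrix"), inherits(test, "score_matrix"))
  if (!identical(predictor_names(train), predictor_names(test))) {
    stop("train and test predictor sets differ", call. = FALSE)
  }
  if (!identical(train$vocabulary$locations, test$vocabulary$locations)) {
    stop("train and test vocabularies differ", call. = FALSE)
  }
  if (is.null(test$labels)) stop("test matrix must be labeled", call. = FALSE)
  base_reports <- per_predictor_report(
    if (select_on == "test") test else train)
  locs <- train$vocabulary$locations
  rows <- lapply(cases, function(case) {
    committee <- select_committee(base_reports, case)
    row <- data.frame(case_id = case$case_id,
                      committee = paste(committee, collapse = ","),
                      n_predictors = length(committee),
                      stringsAsFactors = FALSE)
    if (length(committee) == 0L) {
      for (loc in locs) row[[loc]] <- NA_real_
      row$overall <- NA_real_
      row$train_fitness <- NA_real_
      return(row)
    }
    fit <- fit_consensus(subset_predictors(train, committee), config,
                         weights_per = weights_per)
    pred <- consensus_predict(subset_predictors(test, committee),
                              fit$weights)
    rep <- accuracy_report(pred$predicted, test$labels, test$vocabulary,
                           case$case_id)
    for (loc in locs) row[[loc]] <- rep$per_class[[loc]]
    row$overall <- rep$overall
    row$train_fitness <- fit$fitness
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
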