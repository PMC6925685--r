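#' Fusion weight vector
#'
#' The decision variables of the consensus: one weight per predictor
#' (`per_predictor`, dimension `n`) or one weight per predictor and
#' location (`per_class`, dimension `n * m`, predictor-major order).
#' The per-class layout subsumes the per-predictor one and lets the
#' optimizer trust a tool on the compartments it is good at while
#' discounting it elsewhere.
#'
#' @param values Numeric weights, length `n` or `n * m`.
#' @param mode `"per_class"` or `"per_predictor"`.
#' @param predictors Character vector of predictor names (length `n`).
#' @param vocabulary A [location_vocabulary()].
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(values, mode = c("per_class", "per_predictor"),
                          predictors, vocabulary) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocabulary, "location_vocabulary"))
  n <- length(predictors)
  m <- length(vocabulary$locations)
  expected <- if (mode == "per_predictor") n else n * m
  if (length(values) != expected) {
    stop("weight vector must have length ", expected, " in ", mode,
         " mode (got ", length(values), ")", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("weights must be finite", call. = FALSE)
  names(values) <- if (mode == "per_predictor") predictors else
    paste(rep(predictors, each = m), rep(vocabulary$locations, n), sep = "__")
  structure(list(values = values, mode = mode, predictors = predictors,
                 vocabulary = vocabulary),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> mode ", x$mode, ", ", length(x$values),
      " weights over ", length(x$predictors), " predictors\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

.check_weights_compatible <- function(matrix, weights) {
  stopifnot(inherits(matrix, "score_matrix"),
            inherits(weights, "weight_vector"))
  a <- predictor_names(matrix)
  b <- weights$predictors
  if (!identical(a, b)) {
    only_m <- setdiff(a, b)
    only_w <- setdiff(b, a)
    stop("predictor sets differ between score matrix and weights.",
         if (length(only_m)) paste0(" Only in matrix: ",
                                    paste(only_m, collapse = ", "), "."),
         if (length(only_w)) paste0(" Only in weights: ",
                                    paste(only_w, collapse = ", "), "."),
         if (!length(only_m) && !length(only_w)) " Order differs.",
         call. = FALSE)
  }
  if (!identical(matrix$vocabulary$locations, weights$vocabulary$locations)) {
    stop("location vocabularies differ between score matrix and weights",
         call. = FALSE)
  }
}

#' Weighted score combination
#'
#' Computes the combined per-location score vector for every sequence:
#' element `j` is `sum_i w_i * x_{i,j}` (per-predictor mode) or
#' `sum_i w_{i,j} * x_{i,j}` (per-class mode), where `x_{i,j}` is
#' predictor `i`'s normalized score for location `j`.
#'
#' @param matrix A [score_matrix()].
#' @param weights A [weight_vector()] compatible with `matrix`.
#' @return Numeric matrix `n_seq x m` of combined scores.
#' @export
combine_scores <- function(matrix, weights) {
  .check_weights_compatible(matrix, weights)
  m <- length(matrix$vocabulary$locations)
  n <- n_predictors(matrix)
  if (weights$mode == "per_predictor") {
    X <- .score_array(matrix)
    out <- base::matrix(base::matrix(X, ncol = n) %*% weights$values,
                        nrow = n_sequences(matrix), ncol = m)
  } else {
    W <- base::matrix(weights$values, nrow = n, ncol = m, byrow = TRUE)
    out <- base::matrix(0, n_sequences(matrix), m)
    for (i in seq_len(n)) {
      out <- out + matrix$scores[[i]] *
        base::matrix(W[i, ], n_sequences(matrix), m, byrow = TRUE)
    }
  }
  dimnames(out) <- list(matrix$sequence_ids, matrix$vocabulary$locations)
  out
}

#' Argmax decision rule
#'
#' A sequence is assigned to the location with the maximum combined
#' score. Ties are broken deterministically by canonical vocabulary
#' order (the first listed location wins); an all-zero vector therefore
#' falls to the first canonical location and should be treated as a
#' low-confidence call.
#'
#' @param combined Numeric vector of length `m`, or an `n_seq x m`
#'   matrix of combined scores.
#' @param vocabulary A [location_vocabulary()].
#' @return Character vector of canonical locations.
#' @export
decide_location <- function(combined, vocabulary) {
  stopifnot(inherits(vocabulary, "location_vocabulary"))
  if (is.null(dim(combined))) combined <- matrix(combined, nrow = 1)
  if (ncol(combined) != length(vocabulary$locations)) {
    stop("combined score vector length must equal the number of locations",
         call. = FALSE)
  }
  if (nrow(combined) == 0L) return(character(0))
  vocabulary$locations[max.col(combined, ties.method = "first")]
}

#' Classification accuracy
#'
#' Fraction of sequences whose predicted location equals the true
#' label: correct answers over instances.
#'
#' @param predictions,labels Character vectors of equal nonzero length.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  if (length(predictions) == 0L) {
    stop("cannot compute accuracy on empty input", call. = FALSE)
  }
  mean(predictions == labels)
}

#' Consensus predictions with confidence scores
#'
#' Applies the weighted combination and the argmax decision to every
#' sequence. Confidence is the L1-normalized combined score vector (a
#' monotone, ranking-preserving mapping); when the combined vector is
#' all-zero the confidence is uniform and the sequence is flagged
#' `low_confidence`, as are exact ties for the top score. The
#' second-ranked location is reported as a candidate alternative
#' compartment for multi-location proteins.
#'
#' @param matrix A [score_matrix()].
#' @param weights A [weight_vector()].
#' @return A data frame with one row per sequence: `sequence_id`,
#'   `predicted`, `runner_up`, one `conf_<location>` column per
#'   location, `low_confidence`, and (when labels are present) `label`
#'   and `correct`. The overall accuracy, when computable, is attached
#'   as attribute `"accuracy"`.
#' @export
consensus_predict <- function(matrix, weights) {
  combined <- combine_scores(matrix, weights)
  m <- ncol(combined)
  locs <- matrix$vocabulary$locations
  predicted <- decide_location(combined, matrix$vocabulary)
  runner_up <- apply(combined, 1L, function(v) locs[order(-v)[2L]])
  if (n_sequences(matrix) == 0L) runner_up <- character(0)
  totals <- rowSums(combined)
  conf <- combined
  pos <- totals > 0
  conf[pos, ] <- conf[pos, , drop = FALSE] / totals[pos]
  conf[!pos, ] <- 1 / m
  top2 <- t(apply(combined, 1L, function(v) sort(v, decreasing = TRUE)[1:2]))
  low_conf <- totals == 0 | top2[, 1] == top2[, 2]
  out <- data.frame(sequence_id = matrix$sequence_ids,
                    predicted = predicted, runner_up = runner_up,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) out[[paste0("conf_", locs[j])]] <- conf[, j]
  out$low_confidence <- as.logical(low_conf)
  if (!is.null(matrix$labels)) {
    out$label <- matrix$labels
    out$correct <- out$predicted == out$label
    if (nrow(out)) attr(out, "accuracy") <- accuracy(predicted, matrix$labels)
  }
  out
}

# training objective: consensus accuracy as a function of the raw
# weight vector; closed over precomputed blocks for speed
.make_objective <- function(matrix, mode) {
  if (is.null(matrix$labels)) {
    stop("weight optimization requires a labeled score matrix", call. = FALSE)
  }
  m <- length(matrix$vocabulary$locations)
  n <- n_predictors(matrix)
  n_seq <- n_sequences(matrix)
  truth <- match(matrix$labels, matrix$vocabulary$locations)
  if (mode == "per_predictor") {
    Xmat <- matrix(.score_array(matrix), ncol = n)
    function(w) {
      combined <- matrix(Xmat %*% w, n_seq, m)
      mean(max.col(combined, ties.method = "first") == truth)
    }
  } else {
    blocks <- matrix$scores
    function(w) {
      W <- matrix(w, n, m, byrow = TRUE)
      combined <- matrix(0, n_seq, m)
      for (i in seq_len(n)) {
        combined <- combined + blocks[[i]] * matrix(W[i, ], n_seq, m,
                                                    byrow = TRUE)
      }
      mean(max.col(combined, ties.method = "first") == truth)
    }
  }
}

# corner starts: particle i weights only predictor i (all its
# dimensions at 1, everything else 0)
.corner_positions <- function(n, m, mode) {
  if (mode == "per_predictor") return(diag(n))
  corners <- matrix(0, n, n * m)
  for (i in seq_len(n)) corners[i, ((i - 1) * m + 1):(i * m)] <- 1
  corners
}

#' Fit the consensus classifier by particle swarm optimization
#'
#' Learns fusion weights that maximize training accuracy of the
#' weighted-sum argmax decision. The first `n` particles are seeded at
#' predictor "corners" (full weight on a single predictor), which
#' guarantees the fitted consensus never scores below the best
#' individual predictor on the training data; the remaining particles
#' start uniformly at random in the weight box.
#'
#' @param matrix A labeled [score_matrix()].
#' @param config A [swarm_config()].
#' @param weights_per `"class"` (default; one weight per predictor and
#'   location) or `"predictor"` (one weight per predictor).
#' @param fixed Optional named numeric vector of per-predictor weights
#'   to freeze during optimization (all of that predictor's dimensions
#'   are pinned to the given value).
#' @return An object of class `consensus_fit`: `weights` (a
#'   [weight_vector()]), `fitness` (training accuracy of the returned
#'   weights), `history` (running global best per objective call),
#'   `calls`, `config`.
#' @examples
#' sc <- table2_like_scenario("gram_positive", seed = 7, n_sequences = 60)
#' mat <- simulate_committee(sc)
#' fit <- fit_consensus(mat, swarm_config(max_calls = 150, seed = 7))
#' fit$fitness
#' @export
fit_consensus <- function(matrix, config = swarm_config(),
                          weights_per = c("class", "predictor"),
                          fixed = NULL) {
  weights_per <- match.arg(weights_per)
  mode <- if (weights_per == "class") "per_class" else "per_predictor"
  n <- n_predictors(matrix)
  m <- length(matrix$vocabulary$locations)
  if (n < 1) stop("no predictors in score matrix", call. = FALSE)
  d <- if (mode == "per_predictor") n else n * m
  objective <- .make_objective(matrix, mode)
  fixed_vec <- NULL
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), predictor_names(matrix))
    if (length(unknown)) {
      stop("fixed weights name unknown predictor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    fixed_vec <- rep(NA_real_, d)
    for (p in names(fixed)) {
      i <- match(p, predictor_names(matrix))
      idx <- if (mode == "per_predictor") i else ((i - 1) * m + 1):(i * m)
      fixed_vec[idx] <- fixed[[p]]
    }
  }
  res <- pso_optimize(objective, d, config,
                      init = .corner_positions(n, m, mode),
                      fixed = fixed_vec)
  structure(list(weights = weight_vector(res$par, mode,
                                         predictor_names(matrix),
                                         matrix$vocabulary),
                 fitness = res$value, history = res$history,
                 calls = res$calls, config = config),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat("<consensus_fit> training accuracy ", format(x$fitness, digits = 4),
      " after ", x$calls, " objective calls (", x$weights$mode,
      " weights, ", length(x$weights$predictors), " predictors)\n", sep = "")
  invisible(x)
}

#' @param object A `consensus_fit`.
#' @param newdata A [score_matrix()] over the same predictor committee.
#' @param ... Unused.
#' @rdname fit_consensus
#' @export
predict.consensus_fit <- function(object, newdata, ...) {
  consensus_predict(newdata, object$weights)
}
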