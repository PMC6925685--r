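#' Normalize a per-sequence score vector
#'
#' Per-sequence L1 normalization: scores are divided by their sum so
#' probabilistic and one-hot predictors live on the same scale. An
#' all-zero vector (a predictor abstaining on a sequence) is returned
#' unchanged so the predictor contributes nothing to the consensus sum.
#'
#' @param raw Numeric vector of finite, nonnegative scores.
#' @return Numeric vector summing to 1 (or all-zero), same order.
#' @export
normalize_scores <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop("scores must be finite numbers", call. = FALSE)
  }
  if (any(raw < 0)) stop("scores must be nonnegative", call. = FALSE)
  s <- sum(raw)
  if (s > 0) raw / s else raw
}

# row-wise L1 normalization of an n_seq x m matrix; all-zero rows kept
.normalize_rows <- function(mat) {
  s <- rowSums(mat)
  keep <- s > 0
  mat[keep, ] <- mat[keep, , drop = FALSE] / s[keep]
  mat
}

#' Construct a score matrix
#'
#' The central container: per-sequence, per-predictor, per-location
#' normalized scores, with optional true labels for training. Each
#' predictor contributes an `n_seq x m` matrix whose rows sum to 1 (or
#' are all-zero abstentions); `m` and column order come from the
#' vocabulary.
#'
#' @param scores Named list of numeric matrices (`n_seq x m`), one per
#'   predictor, in committee order.
#' @param vocabulary A [location_vocabulary()].
#' @param sequence_ids Character vector of unique sequence identifiers.
#' @param labels Optional character vector of true locations (aliases
#'   accepted; resolved to canonical names).
#' @param normalize Normalize rows on construction (default `TRUE`).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(scores, vocabulary, sequence_ids, labels = NULL,
                         normalize = TRUE) {
  stopifnot(inherits(vocabulary, "location_vocabulary"),
            is.list(scores), length(scores) >= 1L)
  if (is.null(names(scores)) || anyNA(names(scores)) ||
      any(names(scores) == "") || anyDuplicated(names(scores))) {
    stop("scores must be a list with unique, nonempty predictor names",
         call. = FALSE)
  }
  sequence_ids <- as.character(sequence_ids)
  if (anyDuplicated(sequence_ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(sequence_ids[duplicated(sequence_ids)]), collapse = ", "),
         call. = FALSE)
  }
  m <- length(vocabulary$locations)
  n_seq <- length(sequence_ids)
  scores <- lapply(scores, function(x) {
    x <- as.matrix(x)
    if (!identical(dim(x), c(n_seq, m)) &&
        !(n_seq == 0L && ncol(x) == m)) {
      stop("each predictor's score block must be ", n_seq, " x ", m,
           call. = FALSE)
    }
    if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
      stop("scores must be finite and nonnegative", call. = FALSE)
    }
    storage.mode(x) <- "double"
    dimnames(x) <- list(sequence_ids, vocabulary$locations)
    if (normalize) x <- .normalize_rows(x)
    x
  })
  if (!is.null(labels)) {
    if (length(labels) != n_seq) {
      stop("labels must match the number of sequences", call. = FALSE)
    }
    labels <- resolve_location(labels, vocabulary)
  }
  structure(list(sequence_ids = sequence_ids, vocabulary = vocabulary,
                 scores = scores, labels = labels),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", length(x$sequence_ids), " sequences, ",
      length(x$scores), " predictors (",
      paste(names(x$scores), collapse = ", "), "), ",
      x$vocabulary$kind, " (", length(x$vocabulary$locations),
      " locations), labels: ",
      if (is.null(x$labels)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @rdname score_matrix
#' @param x A `score_matrix`.
#' @export
n_predictors <- function(x) length(x$scores)

#' @rdname score_matrix
#' @export
n_sequences <- function(x) length(x$sequence_ids)

#' @rdname score_matrix
#' @export
predictor_names <- function(x) names(x$scores)

#' Restrict a score matrix to a sub-committee
#'
#' @param x A `score_matrix`.
#' @param predictors Character vector of predictor names to keep, in
#'   the order given.
#' @return A `score_matrix` over the selected predictors.
#' @export
subset_predictors <- function(x, predictors) {
  stopifnot(inherits(x, "score_matrix"))
  missing <- setdiff(predictors, names(x$scores))
  if (length(missing)) {
    stop("unknown predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$scores <- x$scores[predictors]
  x
}

#' Read a score matrix from CSV
#'
#' Expected dialect: UTF-8, comma-separated, header row with columns
#' `sequence_id`, optional `label`, then one column per
#' predictor-location pair named `<predictor>__<location>` (double
#' underscore). Predictors that do not cover some locations (a
#' 3-location tool inside a 5-location committee) simply omit those
#' columns; the missing locations are filled with 0. All rows are
#' L1-normalized on load.
#'
#' @param path CSV file path.
#' @param vocabulary A [location_vocabulary()].
#' @return A `score_matrix`.
#' @export
read_score_matrix <- function(path, vocabulary) {
  stopifnot(inherits(vocabulary, "location_vocabulary"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sequence_id" %in% names(df)) {
    stop("missing required column 'sequence_id' in ", path, call. = FALSE)
  }
  seq_ids <- as.character(df$sequence_id)
  if (anyDuplicated(seq_ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(seq_ids[duplicated(seq_ids)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- if ("label" %in% names(df)) as.character(df$label) else NULL
  score_cols <- setdiff(names(df), c("sequence_id", "label"))
  if (!length(score_cols)) stop("no predictor score columns found", call. = FALSE)
  parts <- regmatches(score_cols, regexpr("__", score_cols), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("score columns must be named <predictor>__<location>; offending: ",
         paste(score_cols[bad], collapse = ", "), call. = FALSE)
  }
  preds <- vapply(parts, `[`, "", 1L)
  locs <- resolve_location(vapply(parts, `[`, "", 2L), vocabulary)
  m <- length(vocabulary$locations)
  n_seq <- nrow(df)
  scores <- list()
  for (p in unique(preds)) {
    block <- matrix(0, n_seq, m,
                    dimnames = list(seq_ids, vocabulary$locations))
    for (k in which(preds == p)) {
      col <- suppressWarnings(as.numeric(df[[score_cols[k]]]))
      if (anyNA(col) || any(!is.finite(col))) {
        stop("non-numeric or non-finite scores in column ",
             sQuote(score_cols[k]), call. = FALSE)
      }
      block[, locs[k]] <- col
    }
    scores[[p]] <- block
  }
  score_matrix(scores, vocabulary, seq_ids, labels = labels)
}

#' Write a score matrix to CSV
#'
#' Inverse of [read_score_matrix()]: reading the written file
#' reproduces the matrix up to floating-point formatting.
#'
#' @param x A `score_matrix`.
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "score_matrix"))
  df <- data.frame(sequence_id = x$sequence_ids, stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$label <- x$labels
  for (p in names(x$scores)) {
    block <- x$scores[[p]]
    for (loc in x$vocabulary$locations) {
      df[[paste0(p, "__", loc)]] <- block[, loc]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# stack predictor blocks into an n_seq x m x n array (predictor last)
.score_array <- function(x) {
  m <- length(x$vocabulary$locations)
  array(unlist(x$scores, use.names = FALSE),
        dim = c(length(x$sequence_ids), m, length(x$scores)),
        dimnames = list(x$sequence_ids, x$vocabulary$locations,
                        names(x$scores)))
}

# one predictor marked label-only iff every row is one-hot or abstaining
.is_label_only <- function(block) {
  all(block %in% c(0, 1)) && all(rowSums(block) %in% c(0, 1))
}
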