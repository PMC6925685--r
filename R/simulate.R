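#' Synthetic base-predictor profile
#'
#' A predictor is characterized by an `m x m` row-stochastic confusion
#' matrix (row = true class, column = the class the predictor's argmax
#' lands on; the diagonal is its expected per-class accuracy) and, for
#' probabilistic predictors, a concentration governing how sharply the
#' emitted score vector peaks on the emitted class.
#'
#' @param name Predictor name.
#' @param mode `"probabilistic"` or `"label_only"`.
#' @param confusion `m x m` row-stochastic matrix.
#' @param concentration Positive sharpness (probabilistic mode only);
#'   larger values concentrate more score mass on the emitted class.
#' @return An object of class `predictor_profile`.
#' @export
predictor_profile <- function(name, mode = c("probabilistic", "label_only"),
                              confusion, concentration = 5) {
  mode <- match.arg(mode)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion rows must be nonnegative and sum to 1", call. = FALSE)
  }
  stopifnot(concentration > 0)
  structure(list(name = name, mode = mode, confusion = confusion,
                 concentration = concentration),
            class = "predictor_profile")
}

#' Synthetic committee scenario
#'
#' Defines the study conditions for a simulated committee: the
#' vocabulary, class priors, predictor profiles, number of sequences
#' and the seed. `correlation` optionally couples the predictors'
#' correct/incorrect draws through a shared per-sequence difficulty
#' (default 0: errors are independent across predictors, the regime in
#' which fusion has the most to gain).
#'
#' @param vocabulary A [location_vocabulary()].
#' @param profiles List of [predictor_profile()] objects whose
#'   confusion matrices are `m x m` for this vocabulary.
#' @param n_sequences Number of sequences to simulate.
#' @param class_priors Length-`m` probability vector (default uniform).
#' @param seed Integer seed; generation is fully reproducible.
#' @param correlation Probability, per predictor and sequence, of using
#'   the shared difficulty draw instead of an independent one.
#' @return An object of class `committee_scenario`.
#' @export
committee_scenario <- function(vocabulary, profiles, n_sequences,
                               class_priors = NULL, seed = 1L,
                               correlation = 0) {
  stopifnot(inherits(vocabulary, "location_vocabulary"),
            n_sequences >= 1, correlation >= 0, correlation <= 1)
  m <- length(vocabulary$locations)
  if (is.null(class_priors)) class_priors <- rep(1 / m, m)
  if (length(class_priors) != m || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-9) {
    stop("class_priors must be a length-", m, " probability vector",
         call. = FALSE)
  }
  for (p in profiles) {
    stopifnot(inherits(p, "predictor_profile"))
    if (nrow(p$confusion) != m) {
      stop("profile ", p$name, " confusion is not ", m, " x ", m,
           call. = FALSE)
    }
  }
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate profile names", call. = FALSE)
  names(profiles) <- nms
  structure(list(vocabulary = vocabulary, class_priors = class_priors,
                 profiles = profiles, n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed), correlation = correlation),
            class = "committee_scenario")
}

# sharpened simplex draw: Dirichlet(1,...,1) mixed with the one-hot of
# the emitted class; the max entry is swapped into the emitted slot if
# needed so the argmax contract holds for every concentration
.emit_prob_scores <- function(emitted, m, concentration) {
  n <- length(emitted)
  g <- matrix(stats::rexp(n * m), n, m)
  dir <- g / rowSums(g)
  lambda <- concentration / (1 + concentration)
  sc <- (1 - lambda) * dir
  idx <- cbind(seq_len(n), emitted)
  sc[idx] <- sc[idx] + lambda
  top <- max.col(sc, ties.method = "first")
  fix <- which(top != emitted)
  for (r in fix) {
    tmp <- sc[r, top[r]]
    sc[r, top[r]] <- sc[r, emitted[r]]
    sc[r, emitted[r]] <- tmp
  }
  sc
}

#' Generate a synthetic score matrix
#'
#' Labels are drawn from the class priors; for each sequence and
#' predictor an emitted class is drawn from the confusion row of the
#' true class. Label-only predictors contribute the one-hot of the
#' emitted class; probabilistic predictors contribute a normalized
#' random score vector whose argmax is the emitted class.
#'
#' @param scenario A [committee_scenario()].
#' @return A labeled [score_matrix()].
#' @export
simulate_committee <- function(scenario) {
  stopifnot(inherits(scenario, "committee_scenario"))
  set.seed(scenario$seed)
  vocab <- scenario$vocabulary
  m <- length(vocab$locations)
  n_seq <- scenario$n_sequences
  truth <- sample.int(m, n_seq, replace = TRUE, prob = scenario$class_priors)
  shared_u <- stats::runif(n_seq)
  scores <- lapply(scenario$profiles, function(profile) {
    conf <- profile$confusion
    diag_p <- diag(conf)[truth]
    u <- stats::runif(n_seq)
    if (scenario$correlation > 0) {
      use_shared <- stats::runif(n_seq) < scenario$correlation
      u[use_shared] <- shared_u[use_shared]
    }
    correct <- u < diag_p
    emitted <- truth
    for (t in seq_len(m)) {
      wrong <- which(!correct & truth == t)
      if (!length(wrong)) next
      off <- conf[t, ]
      off[t] <- 0
      if (sum(off) <= 0) {
        # row is purely diagonal; a miss is impossible in the limit but
        # the coupling can still land here at p = diag exactly
        correct[wrong] <- TRUE
        next
      }
      emitted[wrong] <- sample.int(m, length(wrong), replace = TRUE,
                                   prob = off / sum(off))
    }
    if (profile$mode == "label_only") {
      block <- matrix(0, n_seq, m)
      block[cbind(seq_len(n_seq), emitted)] <- 1
      block
    } else {
      .emit_prob_scores(emitted, m, profile$concentration)
    }
  })
  score_matrix(scores, vocab,
               sequence_ids = sprintf("seq_%05d", seq_len(n_seq)),
               labels = vocab$locations[truth])
}

# uniform off-diagonal confusion with the given diagonal
.confusion_uniform <- function(diag_acc, m) {
  conf <- matrix(0, m, m)
  for (t in seq_len(m)) {
    conf[t, ] <- (1 - diag_acc[t]) / (m - 1)
    conf[t, t] <- diag_acc[t]
  }
  conf
}

#' Heterogeneous-committee fixture scenario
#'
#' A ready-made committee echoing the skill pattern real localization
#' tools show: no single predictor is best on every compartment, so a
#' weighted consensus can strictly beat each of them. Profiles:
#' \describe{
#'   \item{generalist}{probabilistic; perfect on the first `m - 2`
#'     locations, 50\% on the last two.}
#'   \item{specialist}{probabilistic; perfect on the last two
#'     locations, weak (30\%) elsewhere, with its errors confined to
#'     the first `m - 2` classes so it rarely over-calls its
#'     specialty.}
#'   \item{scattershot}{probabilistic; near-random (30\% everywhere).}
#'   \item{onetrack}{label-only; always emits the second canonical
#'     location, the one-class-dominant pathology.}
#' }
#' By construction every location is covered by some predictor with
#' per-class accuracy exactly 1, while the best individual overall
#' accuracy stays well below 1.
#'
#' @param kind `"gram_negative"` or `"gram_positive"`.
#' @param seed Integer seed.
#' @param n_sequences Number of sequences (default 500).
#' @param correlation Passed to [committee_scenario()].
#' @return A [committee_scenario()] with balanced class priors.
#' @export
table2_like_scenario <- function(kind = c("gram_negative", "gram_positive"),
                                 seed = 1L, n_sequences = 500L,
                                 correlation = 0) {
  kind <- match.arg(kind)
  vocab <- location_vocabulary(kind)
  m <- length(vocab$locations)
  easy <- seq_len(m - 2)          # generalist's strong classes
  hard <- c(m - 1, m)             # specialist's strong classes
  gen_conf <- .confusion_uniform(c(rep(1, m - 2), 0.5, 0.5), m)
  spec_conf <- matrix(0, m, m)
  for (t in easy) {
    spec_conf[t, easy] <- 0.7 / max(1, length(easy) - 1)
    spec_conf[t, t] <- 0.3
    if (length(easy) == 1) spec_conf[t, t] <- 1  # nowhere else to err
  }
  for (t in hard) spec_conf[t, t] <- 1
  spec_conf <- spec_conf / rowSums(spec_conf)
  one_conf <- matrix(0, m, m)
  one_conf[, 2] <- 1
  profiles <- list(
    predictor_profile("generalist", "probabilistic", gen_conf,
                      concentration = 8),
    predictor_profile("specialist", "probabilistic", spec_conf,
                      concentration = 8),
    predictor_profile("scattershot", "probabilistic",
                      .confusion_uniform(rep(0.3, m), m),
                      concentration = 2),
    predictor_profile("onetrack", "label_only", one_conf))
  committee_scenario(vocab, profiles, n_sequences, seed = seed,
                     correlation = correlation)
}
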