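# Shared fixtures, all built in code.

gneg <- location_vocabulary("gram_negative")
gpos <- location_vocabulary("gram_positive")

# tiny deterministic two-predictor matrix: "oracle" is always right,
# "contrarian" always points at the next canonical location
toy_matrix <- function(vocab = gneg, n_seq = 8L) {
  m <- length(vocab$locations)
  truth <- rep(seq_len(m), length.out = n_seq)
  onehot <- function(idx) {
    b <- matrix(0, n_seq, m)
    b[cbind(seq_len(n_seq), idx)] <- 1
    b
  }
  score_matrix(list(oracle = onehot(truth),
                    contrarian = onehot(truth %% m + 1L)),
               vocab, sprintf("s%02d", seq_len(n_seq)),
               labels = vocab$locations[truth])
}

# small random labeled committee for oracle-vs-swarm comparisons
random_instance <- function(seed, n_pred = 2L, m = 2L, n_seq = 12L) {
  set.seed(seed)
  locs <- gneg$locations[seq_len(m)]
  vocab <- gneg
  vocab$locations <- locs
  truth <- sample.int(m, n_seq, replace = TRUE)
  blocks <- lapply(seq_len(n_pred), function(i) {
    raw <- matrix(stats::rexp(n_seq * m), n_seq, m)
    # tilt toward the truth so predictors carry signal
    raw[cbind(seq_len(n_seq), truth)] <-
      raw[cbind(seq_len(n_seq), truth)] + stats::runif(n_seq, 0, 2)
    raw
  })
  names(blocks) <- paste0("p", seq_len(n_pred))
  score_matrix(blocks, vocab, sprintf("s%03d", seq_len(n_seq)),
               labels = locs[truth])
}

# counting wrapper used to assert how many times an objective is called
counted <- function(f) {
  calls <- 0L
  list(fn = function(w) {
    calls <<- calls + 1L
    f(w)
  },
  count = function() calls)
}
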