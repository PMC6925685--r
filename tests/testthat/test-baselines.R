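test_that("majority vote takes the plurality with canonical tie-break", {
  m <- 5
  onehot_block <- function(idx) {
    b <- matrix(0, length(idx), m)
    b[cbind(seq_along(idx), idx)] <- 1
    b
  }
  # seq1: votes (1,1,2) -> 1; seq2: tie (2,3,abstain) -> 2 (earlier);
  # seq3: all abstain -> first canonical location
  mat <- score_matrix(list(
    a = rbind(onehot_block(c(1, 2))[1:2, ], rep(0, m)),
    b = rbind(onehot_block(c(1, 3))[1:2, ], rep(0, m)),
    c = rbind(onehot_block(1)[1, , drop = FALSE], rep(0, m), rep(0, m))),
    gneg, c("s1", "s2", "s3"))
  expect_identical(majority_vote(mat),
                   c("extracellular", "outer_membrane", "extracellular"))
})

test_that("majority vote ignores per-predictor score scaling", {
  mat <- random_instance(31, n_pred = 3, m = 3, n_seq = 20)
  scaled <- mat
  scaled$scores <- lapply(seq_along(mat$scores), function(i) {
    mat$scores[[i]] * c(2, 0.5, 9)[i]
  })
  names(scaled$scores) <- names(mat$scores)
  expect_identical(majority_vote(scaled), majority_vote(mat))
})

test_that("average probability voting is the mean-score argmax", {
  block1 <- matrix(c(0.6, 0.4), 1)
  block2 <- matrix(c(0.2, 0.8), 1)
  vocab <- gneg
  vocab$locations <- gneg$locations[1:2]
  mat <- score_matrix(list(a = block1, b = block2), vocab, "s1")
  expect_identical(average_probability_vote(mat), "outer_membrane")
  single <- score_matrix(list(a = block1), vocab, "s1")
  expect_identical(average_probability_vote(single), "extracellular")
})

test_that("average probability voting equals the uniform-weight consensus", {
  mat <- simulate_committee(table2_like_scenario("gram_negative", seed = 13,
                                                 n_sequences = 80))
  w <- weight_vector(rep(1, n_predictors(mat)), "per_predictor",
                     predictor_names(mat), gneg)
  expect_identical(average_probability_vote(mat),
                   consensus_predict(mat, w)$predicted)
})

test_that("majority and average-probability votes agree on one-hot committees", {
  # exhaustive: every assignment of emitted classes for n <= 3, m <= 3
  # on a single sequence; with one-hot scores the mean vector is the
  # vote-count vector scaled by 1/n, so the argmaxes (and tie-breaks)
  # coincide
  for (m in 2:3) {
    vocab <- gneg
    vocab$locations <- gneg$locations[seq_len(m)]
    for (n in 1:3) {
      combos <- do.call(expand.grid, rep(list(seq_len(m)), n))
      for (r in seq_len(nrow(combos))) {
        blocks <- lapply(seq_len(n), function(i) {
          b <- matrix(0, 1, m)
          b[1, combos[r, i]] <- 1
          b
        })
        names(blocks) <- paste0("p", seq_len(n))
        mat <- score_matrix(blocks, vocab, "s1")
        expect_identical(majority_vote(mat), average_probability_vote(mat))
      }
    }
  }
})

test_that("per-predictor reports recover each tool's skill profile", {
  m <- 5
  n_seq <- 10
  truth <- rep(1:5, 2)
  perfect <- matrix(0, n_seq, m)
  perfect[cbind(1:n_seq, truth)] <- 1
  fixed <- matrix(0, n_seq, m)
  fixed[, 2] <- 1  # always predicts the second location
  mat <- score_matrix(list(perfect = perfect, onetrack = fixed), gneg,
                      sprintf("s%d", 1:n_seq),
                      labels = gneg$locations[truth])
  reports <- per_predictor_report(mat)
  expect_equal(unname(reports$perfect$per_class), rep(1, 5))
  expect_equal(reports$perfect$overall, 1)
  expect_equal(unname(reports$onetrack$per_class), c(0, 1, 0, 0, 0))
  expect_equal(reports$onetrack$overall, 0.2)
})

test_that("classes with no sequences report NA accuracy", {
  block <- matrix(0, 2, 5)
  block[, 5] <- 1
  mat <- score_matrix(list(p = block), gneg, c("a", "b"),
                      labels = c("cytoplasm", "cytoplasm"))
  rep <- per_predictor_report(mat)$p
  expect_true(is.na(rep$per_class[["periplasm"]]))
  expect_equal(rep$per_class[["cytoplasm"]], 1)
})

test_that("overall accuracy is the label-weighted mean of per-class accuracies", {
  mat <- simulate_committee(table2_like_scenario("gram_positive", seed = 17,
                                                 n_sequences = 120))
  for (rep in per_predictor_report(mat, include_fusion = TRUE)) {
    freqs <- table(factor(mat$labels, levels = gpos$locations))
    pc <- rep$per_class
    pc[is.na(pc)] <- 0
    expect_equal(rep$overall,
                 sum(pc * as.numeric(freqs)) / length(mat$labels))
  }
})

test_that("report_table lays out methods by location plus overall", {
  mat <- toy_matrix()
  tab <- report_table(per_predictor_report(mat, include_fusion = TRUE))
  expect_identical(tab$method[1:2], c("oracle", "contrarian"))
  expect_true(all(gneg$locations %in% names(tab)))
  expect_equal(tab$overall[tab$method == "oracle"], 1)
  expect_equal(tab$overall[tab$method == "contrarian"], 0)
})
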