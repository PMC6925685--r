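test_that("combine_scores implements the weighted sum in both modes", {
  mat <- toy_matrix(gneg, n_seq = 5)
  n <- 2; m <- 5
  # masking weight reproduces predictor 1 exactly
  w1 <- weight_vector(c(1, 0), "per_predictor", predictor_names(mat), gneg)
  expect_equal(combine_scores(mat, w1), mat$scores$oracle)
  # equal weights sum the one-hots
  w11 <- weight_vector(c(1, 1), "per_predictor", predictor_names(mat), gneg)
  expect_equal(combine_scores(mat, w11),
               mat$scores$oracle + mat$scores$contrarian)
  # zero weights annihilate
  w0 <- weight_vector(rep(0, n), "per_predictor", predictor_names(mat), gneg)
  expect_true(all(combine_scores(mat, w0) == 0))
  # per-class masking: keep predictor 1 only on location 1
  wpc <- weight_vector(c(1, rep(0, 2 * m - 1)), "per_class",
                       predictor_names(mat), gneg)
  expect_equal(unname(combine_scores(mat, wpc)[, 1]),
               unname(mat$scores$oracle[, 1]))
  expect_true(all(combine_scores(mat, wpc)[, -1] == 0))
})

test_that("per-class mode with uniform per-predictor rows equals per-predictor mode", {
  mat <- random_instance(21, n_pred = 3, m = 3, n_seq = 15)
  w <- c(0.2, 0.9, 0.5)
  wp <- weight_vector(w, "per_predictor", predictor_names(mat),
                      mat$vocabulary)
  wc <- weight_vector(rep(w, each = 3), "per_class",
                      predictor_names(mat), mat$vocabulary)
  expect_equal(combine_scores(mat, wp), combine_scores(mat, wc))
})

test_that("decide_location takes the argmax with canonical-order ties", {
  expect_identical(decide_location(c(0.1, 0.7, 0.1, 0.05, 0.05), gneg),
                   "outer_membrane")
  expect_identical(decide_location(c(0.5, 0.5, 0, 0, 0), gneg),
                   "extracellular")
  expect_identical(decide_location(rep(0, 5), gneg), "extracellular")
  expect_error(decide_location(c(0.5, 0.5), gneg), "length")
})

test_that("accuracy counts exact matches over instances", {
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 0.75)
  expect_equal(accuracy(letters[1:5], letters[1:5]), 1)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy("a", c("a", "b")), "length")
})

test_that("consensus predictions are scale invariant with unit confidence", {
  mat <- simulate_committee(table2_like_scenario("gram_positive", seed = 8,
                                                 n_sequences = 40))
  w <- weight_vector(runif(4 * 4, 0.1, 1), "per_class",
                     predictor_names(mat), gpos)
  pred <- consensus_predict(mat, w)
  w2 <- w
  w2$values <- w$values * 7.3
  pred2 <- consensus_predict(mat, w2)
  expect_identical(pred$predicted, pred2$predicted)
  conf <- as.matrix(pred[, paste0("conf_", gpos$locations)])
  expect_equal(unname(rowSums(conf)), rep(1, nrow(pred)))
  expect_true(all(pred$correct == (pred$predicted == pred$label)))
})

test_that("corner weights reproduce a predictor's standalone argmax", {
  mat <- simulate_committee(table2_like_scenario("gram_negative", seed = 2,
                                                 n_sequences = 50))
  n <- n_predictors(mat); m <- 5
  for (i in seq_len(n)) {
    v <- rep(0, n * m)
    v[((i - 1) * m + 1):(i * m)] <- 1
    w <- weight_vector(v, "per_class", predictor_names(mat), gneg)
    expect_identical(consensus_predict(mat, w)$predicted,
                     decide_location(mat$scores[[i]], gneg))
  }
})

test_that("unanimous one-hot committees are predicted under any positive weighting", {
  m <- 5
  block <- matrix(0, 3, m)
  block[cbind(1:3, c(3, 1, 5))] <- 1
  mat <- score_matrix(list(a = block, b = block, c = block), gneg,
                      c("x", "y", "z"))
  set.seed(1)
  for (k in 1:5) {
    w <- weight_vector(runif(3, 0.05, 1), "per_predictor",
                       predictor_names(mat), gneg)
    expect_identical(consensus_predict(mat, w)$predicted,
                     gneg$locations[c(3, 1, 5)])
  }
})

test_that("all-zero combined vectors fall to the first location, flagged", {
  block <- matrix(0, 2, 5)
  block[1, 3] <- 1
  mat <- score_matrix(list(p = block), gneg, c("a", "b"))
  w <- weight_vector(1, "per_predictor", "p", gneg)
  pred <- consensus_predict(mat, w)
  expect_identical(pred$predicted[2], "extracellular")
  expect_true(pred$low_confidence[2])
  expect_false(pred$low_confidence[1])
  expect_equal(as.numeric(pred[2, paste0("conf_", gneg$locations)]),
               rep(0.2, 5))
})

test_that("weights incompatible with the committee are rejected with the diff", {
  mat <- toy_matrix()
  w <- weight_vector(c(1, 1), "per_predictor", c("oracle", "stranger"), gneg)
  expect_error(consensus_predict(mat, w), "stranger")
  expect_error(consensus_predict(mat, w), "contrarian")
})
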