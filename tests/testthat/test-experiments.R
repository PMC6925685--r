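fake_report <- function(name, overall) {
  structure(list(method_name = name,
                 per_class = NULL, overall = overall, n_sequences = 100),
            class = "accuracy_report")
}

reports_abc <- list(fake_report("A", 0.97), fake_report("B", 0.85),
                    fake_report("C", 0.60))

test_that("committee selection applies each ablation rule", {
  expect_identical(select_committee(reports_abc,
                                    ablation_case("keep_ge_threshold", 0.9)),
                   "A")
  expect_identical(select_committee(reports_abc, ablation_case("drop_best")),
                   c("B", "C"))
  expect_identical(select_committee(reports_abc,
                                    ablation_case("keep_lt_threshold", 0.6)),
                   character(0))
  # threshold is inclusive on the keep-ge side
  expect_identical(select_committee(reports_abc,
                                    ablation_case("keep_ge_threshold", 0.6)),
                   c("A", "B", "C"))
})

test_that("drop_best removes the first of tied best predictors", {
  tied <- list(fake_report("X", 0.9), fake_report("Y", 0.9),
               fake_report("Z", 0.5))
  expect_identical(select_committee(tied, ablation_case("drop_best")),
                   c("Y", "Z"))
})

test_that("keep-ge and keep-lt partition the committee at every threshold", {
  set.seed(99)
  reports <- lapply(1:6, function(i) fake_report(paste0("p", i), runif(1)))
  nms <- paste0("p", 1:6)
  for (t in c(0.3, 0.5, 0.62, 0.9)) {
    ge <- select_committee(reports, ablation_case("keep_ge_threshold", t))
    lt <- select_committee(reports, ablation_case("keep_lt_threshold", t))
    expect_length(intersect(ge, lt), 0)
    expect_setequal(c(ge, lt), nms)
  }
})

test_that("the canonical grid has nine cases with the standard thresholds", {
  cases <- canonical_ablation_cases()
  expect_length(cases, 9L)
  expect_identical(cases[[1]]$rule, "drop_best")
  ths <- vapply(cases[-1], `[[`, numeric(1), "threshold")
  expect_equal(unname(ths), rep(c(0.9, 0.8, 0.7, 0.6), each = 2))
})

test_that("ablation cases validate their threshold argument", {
  expect_error(ablation_case("keep_ge_threshold"), "threshold")
  expect_error(ablation_case("keep_lt_threshold", 1.5), "threshold")
  expect_error(ablation_case("drop_best", 0.9), "no threshold")
})

test_that("the ablation grid refits per case and marks untestable cases NA", {
  cfg <- swarm_config(max_calls = 120, n_particles = 10, seed = 6)
  sc_train <- table2_like_scenario("gram_positive", seed = 61,
                                   n_sequences = 120)
  sc_test <- table2_like_scenario("gram_positive", seed = 62,
                                  n_sequences = 120)
  train <- simulate_committee(sc_train)
  test <- simulate_committee(sc_test)
  cases <- list(ablation_case("drop_best"),
                ablation_case("keep_ge_threshold", 0.5),
                ablation_case("keep_lt_threshold", 0.01))
  grid <- run_ablation_grid(train, test, cases, cfg)
  expect_identical(nrow(grid), 3L)
  # no predictor sits below 1% accuracy: untestable, all-NA row
  expect_true(is.na(grid$overall[3]))
  expect_identical(grid$n_predictors[3], 0L)
  expect_false(anyNA(grid$overall[1:2]))
  # reproducible under the same config seed
  grid2 <- run_ablation_grid(train, test, cases, cfg)
  expect_identical(grid, grid2)
})

test_that("a single-predictor committee scores exactly that predictor", {
  cfg <- swarm_config(max_calls = 60, n_particles = 8, seed = 3)
  train <- simulate_committee(table2_like_scenario("gram_negative",
                                                   seed = 71,
                                                   n_sequences = 100))
  test <- simulate_committee(table2_like_scenario("gram_negative",
                                                  seed = 72,
                                                  n_sequences = 100))
  # generalist is the only tool at or above 70% on this test split
  grid <- run_ablation_grid(train, test,
                            list(ablation_case("keep_ge_threshold", 0.7)),
                            cfg, weights_per = "predictor")
  expect_identical(grid$committee, "generalist")
  solo <- per_predictor_report(test)$generalist
  expect_equal(grid$overall, solo$overall)
})

test_that("a committee containing a perfect predictor stays perfect", {
  mat_tr <- toy_matrix(gneg, n_seq = 20)
  mat_te <- toy_matrix(gneg, n_seq = 15)
  grid <- run_ablation_grid(mat_tr, mat_te,
                            list(ablation_case("keep_ge_threshold", 0.9)),
                            swarm_config(max_calls = 50, seed = 2))
  expect_identical(grid$committee, "oracle")
  expect_equal(grid$overall, 1)
})

test_that("mismatched train/test committees are rejected", {
  train <- toy_matrix()
  test <- subset_predictors(toy_matrix(), "oracle")
  expect_error(run_ablation_grid(train, test), "differ")
})
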