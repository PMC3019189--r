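# a model whose decoding is forced by delta emissions: symbol 'f' can only
# come from state F, 'l' only from state L
forced_model <- function() {
  states <- c("Start", "F", "L", "End")
  trans <- matrix(0, 4, 4, dimnames = list(states, states))
  trans[1, 2:3] <- 0.5
  trans[2, 2:4] <- c(0.45, 0.45, 0.1)
  trans[3, 2:4] <- c(0.45, 0.45, 0.1)
  emit <- matrix(0, 4, 2, dimnames = list(states, c("f", "l")))
  emit[2, 1] <- 1
  emit[3, 2] <- 1
  hmm_model(states, c("f", "l"), trans, emit, state_labels = c(F = "F", L = "L"))
}

test_that("perfect prediction scores one on every component", {
  m <- forced_model()
  ds <- tibble::tibble(id = "r1", sequence = "fllf", labels = "FLLF")
  sc <- decode_and_score(m, ds, positive_labels = "L")
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  expect_equal(sc$performance, 1)
})

test_that("the confusion table matches a hand count", {
  m <- forced_model()
  # truth LFLF vs prediction LLFF: TP=1, FN=1, FP=1, TN=1
  ds <- tibble::tibble(id = "r1", sequence = "llff", labels = "LFLF")
  sc <- decode_and_score(m, ds, positive_labels = "L")
  expect_equal(c(sc$tp, sc$fn, sc$fp, sc$tn), c(1, 1, 1, 1))
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$specificity, 0.5)
  expect_equal(sc$performance, 0.25)
  # precision convention gives the same number here
  sc2 <- decode_and_score(m, ds, positive_labels = "L",
                          specificity_mode = "precision")
  expect_equal(sc2$specificity, 0.5)
})

test_that("an all-negative prediction has zero sensitivity and performance", {
  m <- forced_model()
  ds <- tibble::tibble(id = "r1", sequence = "ffff", labels = "LFLF")
  sc <- decode_and_score(m, ds, positive_labels = "L")
  expect_equal(sc$sensitivity, 0)
  expect_equal(sc$performance, 0)
})

test_that("missing labels are rejected", {
  m <- forced_model()
  ds <- tibble::tibble(id = "r1", sequence = "ffff")
  expect_error(decode_and_score(m, ds, "L"), "labels")
})

test_that("parameter distances split by kind and vanish on exact recovery", {
  ex <- build_toy2()
  pd0 <- parameter_distance(ex$true_values, ex$true_values, ex$parameterization)
  expect_equal(pd0$emission_distance, 0)
  expect_equal(pd0$transition_distance, 0)

  shifted <- ex$true_values
  shifted[c("t_AA", "t_AB")] <- shifted[c("t_AA", "t_AB")] + c(0.1, -0.1)
  pd <- parameter_distance(shifted, ex$true_values, ex$parameterization)
  # 5 free transition parameters, two moved by 0.1
  expect_equal(pd$transition_distance, 0.2 / 5)
  expect_equal(pd$emission_distance, 0)
})

test_that("the CpG model reports no emission distance", {
  ex <- build_cpg_model()
  pd <- parameter_distance(ex$true_values, ex$true_values, ex$parameterization)
  expect_true(is.na(pd$emission_distance))
  expect_equal(pd$transition_distance, 0)
})

test_that("label-symmetry alignment recognizes the relabeled optimum", {
  ex <- build_dishonest_casino()
  swapped <- ex$true_values
  swap <- ex$symmetries[[1]]
  swapped[names(swap)] <- ex$true_values[swap]
  raw <- parameter_distance(swapped, ex$true_values, ex$parameterization)
  aligned <- parameter_distance(swapped, ex$true_values, ex$parameterization,
                                align = "symmetry", symmetries = ex$symmetries)
  expect_gt(raw$transition_distance, 0)
  expect_equal(aligned$transition_distance, 0)
  expect_equal(aligned$emission_distance, 0)
})

test_that("cross-validation splits are disjoint, exhaustive and reproducible", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 12, length = 20, seed = 8)
  configs <- tibble::tibble(method = c("viterbi", "stochastic_em"), k = c(NA, 1L))
  cv1 <- cross_validate(ex, ds, configs = configs, n_folds = 3, max_iter = 3,
                        seed = 14)
  cv2 <- cross_validate(ex, ds, configs = configs, n_folds = 3, max_iter = 3,
                        seed = 14)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_equal(sort(unique(cv1$folds)), 1:3)
  expect_equal(length(cv1$folds), 12L)
  expect_equal(as.numeric(table(cv1$folds)), rep(4, 3))
  # the performance identity holds on every row
  expect_equal(cv1$metrics$performance,
               cv1$metrics$sensitivity * cv1$metrics$specificity)
  # every fold/config pair reports a contiguous iteration trace; stochastic
  # EM never stops early at tol = 0, Viterbi training may converge sooner
  per <- dplyr::summarise(dplyr::group_by(cv1$metrics, .data$fold, .data$method),
                          n = dplyr::n(), mx = max(.data$iteration),
                          .groups = "drop")
  expect_equal(per$n, per$mx)
  expect_true(all(per$n[per$method == "stochastic_em"] == 3))
  expect_error(cross_validate(ex, ds[1:2, ], configs = configs, n_folds = 3),
               "fewer sequences than folds")
})

test_that("tidy and glance summarize runs and cross-validations", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 6, length = 15, seed = 20)
  run <- viterbi_train(ex$model, ex$parameterization, ds,
                       init = ex$true_values, max_iter = 4)
  td <- tidy(run)
  expect_true(all(c("iteration", "param", "role", "kind", "value", "loglik")
                  %in% names(td)))
  expect_equal(nrow(td), (run$n_iterations + 1) * nrow(ex$parameterization$params))
  gl <- glance(run)
  expect_equal(gl$method, "viterbi")
  expect_equal(gl$n_free_parameters, 7L)
  cv <- cross_validate(ex, ds, configs = tibble::tibble(method = "viterbi", k = NA),
                       n_folds = 2, max_iter = 2, seed = 5)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(run), "ggplot")
  expect_true(all(c("performance_mean", "performance_sd") %in% names(cv$summary)))
})
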