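test_that("the single-path model decodes to its only path with the exact probability", {
  m <- build_toy1()$model
  p <- viterbi_decode(m, "AAB")
  expect_equal(p$states, c("S", "S", "S"))
  expect_equal(exp(p$log_prob), 0.5^3 * 0.6^2 * 0.4, tolerance = 1e-12)
  cnt <- viterbi_counts(m, "AAB")
  expect_equal(cnt$trans["Start", "S"], 1)
  expect_equal(cnt$trans["S", "S"], 2)
  expect_equal(cnt$trans["S", "End"], 1)
  expect_equal(cnt$emit["S", "A"], 2)
  expect_equal(cnt$emit["S", "B"], 1)
  expect_equal(exp(cnt$log_prob), 0.018, tolerance = 1e-12)
})

test_that("decoding matches the brute-force argmax over enumerated paths", {
  m <- build_toy2()$model
  for (x in c("HH", "HT", "TTH", "HTHH")) {
    en <- ref_enumerate(m, x)
    best <- which.max(en$probs)
    p <- viterbi_decode(m, x)
    expect_equal(p$log_prob, log(en$probs[best]), tolerance = 1e-12)
    expect_equal(match(p$states, m$states), unname(en$paths[best, ]))
  }
})

test_that("score ties break toward the lowest previous state index", {
  # fully symmetric two-state model: every path has equal probability
  states <- c("Start", "X", "Y", "End")
  trans <- matrix(0, 4, 4, dimnames = list(states, states))
  trans[1, 2:3] <- 0.5
  trans[2, 2:4] <- 1 / 3
  trans[3, 2:4] <- 1 / 3
  emit <- matrix(0, 4, 2)
  emit[2:3, ] <- 0.5
  m <- hmm_model(states, c("A", "B"), trans, emit)
  p <- viterbi_decode(m, "ABA")
  expect_equal(p$states, c("X", "X", "X"))
  cnt <- viterbi_counts(m, "ABA")
  ref <- path_counts(m, p$states, "ABA")
  expect_equal(cnt$trans, ref$trans)
  expect_equal(cnt$emit, ref$emit)
})

test_that("one-pass counts equal traceback counts on random models", {
  set.seed(101)
  for (i in 1:60) {
    case <- random_case(max_emit = 4, max_sym = 4, max_len = 50)
    p <- viterbi_decode(case$model, case$symbols)
    ref <- path_counts(case$model, p$states, case$symbols)
    cnt <- viterbi_counts(case$model, case$symbols)
    expect_identical(unname(cnt$trans), unname(ref$trans))
    expect_identical(unname(cnt$emit), unname(ref$emit))
    expect_equal(cnt$log_prob, p$log_prob, tolerance = 1e-10)
  }
})

test_that("the one-pass terminal score is the brute-force path maximum", {
  set.seed(102)
  for (i in 1:40) {
    case <- random_case(max_emit = 2, max_sym = 3, max_len = 8)
    cnt <- viterbi_counts(case$model, case$symbols)
    expect_equal(cnt$log_prob, ref_best_log_prob(case$model, case$symbols),
                 tolerance = 1e-10)
  }
})

test_that("count totals are L emissions and L + 1 transitions", {
  set.seed(103)
  for (i in 1:20) {
    case <- random_case(max_len = 30)
    L <- nchar(case$symbols)
    cnt <- viterbi_counts(case$model, case$symbols)
    expect_equal(sum(cnt$emit), L)
    expect_equal(sum(cnt$trans), L + 1)
  }
})

test_that("empty and unreachable sequences raise explicit errors", {
  m <- build_toy1()$model
  expect_error(viterbi_counts(m, ""), "length >= 1")
  # an emission of probability zero makes the sequence unreachable
  states <- c("Start", "S", "End")
  trans <- matrix(0, 3, 3)
  trans[1, 2] <- 1
  trans[2, 2] <- 0.5
  trans[2, 3] <- 0.5
  emit <- matrix(0, 3, 2)
  emit[2, 1] <- 1
  m2 <- hmm_model(states, c("A", "B"), trans, emit)
  expect_error(viterbi_counts(m2, "AB"), "unreachable")
  expect_error(viterbi_decode(m2, "AB"), "unreachable")
})

test_that("single-path data reaches the count fixed point after one update", {
  ex <- build_toy1()
  set.seed(6)
  ds <- generate_dataset(ex, n = 6, length = 10, seed = 31)
  run <- viterbi_train(ex$model, ex$parameterization, ds,
                       init = ex$true_values, max_iter = 10)
  # emission estimate = (symbol count + 1) / (L_total + 2), reached at
  # iteration 1 and stable afterwards
  nA <- sum(unlist(strsplit(ds$sequence, "")) == "A")
  L_tot <- sum(nchar(ds$sequence))
  expect_equal(unname(run$trajectory[2, "e_S_A"]), (nA + 1) / (L_tot + 2))
  expect_equal(run$stop_reason, "paths_converged")
  expect_equal(unname(run$trajectory[run$n_iterations + 1, "e_S_A"]),
               unname(run$trajectory[2, "e_S_A"]))
})

test_that("the training loop equals a two-step decode-and-count reference", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 12, length = 25, seed = 77)
  init <- random_initialize(ex$parameterization, seed = 5)
  run <- viterbi_train(ex$model, ex$parameterization, ds, init = init,
                       max_iter = 6, pseudocount = 1)
  ref <- ref_viterbi_train(ex, ds, init, iterations = run$n_iterations)
  for (q in seq_len(run$n_iterations)) {
    expect_equal(unname(run$trajectory[q + 1, ]),
                 unname(ref[[q]][colnames(run$trajectory)]),
                 tolerance = 1e-12)
  }
})

test_that("strict path-identity convergence is available through the path hash", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 8, length = 20, seed = 13)
  run <- viterbi_train(ex$model, ex$parameterization, ds,
                       init = ex$true_values, max_iter = 25,
                       convergence = "path_hash")
  expect_true(run$stop_reason %in% c("paths_converged", "max_iterations"))
  expect_error(
    train_hmm(ex$model, ex$parameterization, ds, max_iter = 0),
    "max_iter")
})
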