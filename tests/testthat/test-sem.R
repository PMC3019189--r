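test_that("forward probabilities equal brute-force path sums", {
  m1 <- build_toy1()$model
  expect_equal(exp(forward_probability(m1, "AAB")$log_prob), 0.018,
               tolerance = 1e-12)
  m2 <- build_toy2()$model
  for (x in c("HT", "HH", "THT", "HHTT")) {
    fw <- forward_probability(m2, x)
    expect_equal(exp(fw$log_prob), ref_forward_prob(m2, x), tolerance = 1e-10)
    # P(X) <= 1 and P(X) >= best single-path probability
    expect_lte(fw$log_prob, 0)
    expect_gte(fw$log_prob, ref_best_log_prob(m2, x))
  }
  set.seed(201)
  for (i in 1:25) {
    case <- random_case(max_emit = 2, max_sym = 3, max_len = 8)
    fw <- forward_probability(case$model, case$symbols)
    expect_equal(exp(fw$log_prob), ref_forward_prob(case$model, case$symbols),
                 tolerance = 1e-10)
  }
})

test_that("back-tracing returns the unique path when the posterior is a point mass", {
  m <- build_toy1()$model
  fw <- forward_probability(m, "ABA")
  set.seed(8)
  for (p in sample_posterior_paths(m, fw, n = 10)) {
    expect_equal(p, c("S", "S", "S"))
  }
})

test_that("back-traced paths follow the enumerated posterior", {
  m <- build_toy2()$model
  x <- "HT"
  post <- ref_posterior(m, x)
  keys <- apply(post$paths, 1, paste, collapse = "")
  fw <- forward_probability(m, x)
  set.seed(9)
  draws <- sample_posterior_paths(m, fw, n = 4000)
  got <- vapply(draws, function(p) paste(match(p, m$states), collapse = ""),
                character(1))
  obs <- table(factor(got, levels = keys))
  ct <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = post$probs))
  expect_gt(ct$p.value, 0.001)
})

test_that("unreachable states are never selected as predecessors", {
  # state Y can only be entered from Start, so it cannot appear after
  # position 1; no sampled path may visit it later
  states <- c("Start", "X", "Y", "End")
  trans <- matrix(0, 4, 4, dimnames = list(states, states))
  trans[1, 2:3] <- 0.5
  trans[2, c(2, 4)] <- 0.5
  trans[3, c(2, 4)] <- 0.5
  emit <- matrix(0, 4, 2)
  emit[2:3, ] <- 0.5
  m <- hmm_model(states, c("A", "B"), trans, emit)
  fw <- forward_probability(m, "AAA")
  set.seed(10)
  for (p in sample_posterior_paths(m, fw, n = 50)) {
    expect_false("Y" %in% p[-1])
  }
})

test_that("one-pass sampled counts are exact for a point-mass posterior", {
  m <- build_toy1()$model
  set.seed(11)
  sc <- sem_counts(m, "AAB", k = 3)
  expect_equal(exp(sc$log_prob), 0.018, tolerance = 1e-12)
  for (cnt in sc$counts) {
    expect_equal(cnt$trans["S", "S"], 2)
    expect_equal(cnt$trans["S", "End"], 1)
    expect_equal(cnt$emit["S", "A"], 2)
    expect_equal(cnt$emit["S", "B"], 1)
  }
})

test_that("the one-pass sampler reports the same likelihood as the forward pass", {
  set.seed(202)
  for (i in 1:20) {
    case <- random_case(max_len = 30)
    fw <- forward_probability(case$model, case$symbols)
    sc <- sem_counts(case$model, case$symbols, k = 1)
    expect_equal(sc$log_prob, fw$log_prob, tolerance = 1e-10)
  }
})

test_that("one-pass count vectors are distributed as posterior path counts", {
  m <- build_toy2()$model
  x <- "HT"
  post <- ref_posterior(m, x)
  keys <- vapply(seq_along(post$probs), function(i) {
    ref_counts_key(m, post$paths[i, ], post$sym_idx)
  }, character(1))
  # paths with identical count vectors are pooled
  probs <- tapply(post$probs, keys, sum)
  set.seed(12)
  sc <- sem_counts(m, x, k = 6000)
  got <- vapply(sc$counts, counts_key, character(1))
  expect_true(all(got %in% names(probs)))
  obs <- table(factor(got, levels = names(probs)))
  ct <- suppressWarnings(stats::chisq.test(as.numeric(obs),
                                           p = as.numeric(probs)))
  expect_gt(ct$p.value, 0.001)
})

test_that("sampled counts average to the posterior-expected counts", {
  m <- build_toy2()$model
  x <- "HTH"
  set.seed(13)
  k <- 6000
  sc <- sem_counts(m, x, k = k)
  mean_trans <- Reduce(`+`, lapply(sc$counts, `[[`, "trans")) / k
  mean_emit <- Reduce(`+`, lapply(sc$counts, `[[`, "emit")) / k
  fb <- expected_counts(m, x, engine = "forward-backward")
  # binomial-style Monte-Carlo tolerance on each count cell
  tol <- 4 * sqrt(1 / k)
  expect_lt(max(abs(mean_trans - fb$trans)), tol)
  expect_lt(max(abs(mean_emit - fb$emit)), tol)
})

test_that("stochastic EM training is reproducible under a fixed seed", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 10, length = 20, seed = 3)
  r1 <- stochastic_em_train(ex$model, ex$parameterization, ds, k_paths = 3,
                            max_iter = 5, seed = 21, tol = 0)
  r2 <- stochastic_em_train(ex$model, ex$parameterization, ds, k_paths = 3,
                            max_iter = 5, seed = 21, tol = 0)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$loglik, r2$loglik)
})

test_that("on single-path data stochastic EM hits the Viterbi fixed point", {
  ex <- build_toy1()
  ds <- generate_dataset(ex, n = 6, length = 12, seed = 4)
  rs <- stochastic_em_train(ex$model, ex$parameterization, ds, k_paths = 1,
                            init = ex$true_values, max_iter = 3, seed = 1, tol = 0)
  rv <- viterbi_train(ex$model, ex$parameterization, ds,
                      init = ex$true_values, max_iter = 3)
  expect_equal(unname(rs$trajectory[2, ]), unname(rv$trajectory[2, ]),
               tolerance = 1e-12)
})

test_that("one iteration matches the two-step sampler in expectation", {
  ex <- build_toy2()
  ds <- generate_dataset(ex, n = 6, length = 12, seed = 19)
  init <- ex$true_values
  k <- 5
  reps <- 40
  one_pass <- sapply(seq_len(reps), function(r) {
    run <- stochastic_em_train(ex$model, ex$parameterization, ds, k_paths = k,
                               init = init, max_iter = 1, seed = 1000 + r, tol = 0)
    run$trajectory[2, "t_AA"]
  })
  two_step <- sapply(seq_len(reps), function(r) {
    with_seed_test(2000 + r,
                   ref_sem_iteration(ex, ds, init, k = k)[["t_AA"]])
  })
  se <- sqrt(stats::var(one_pass) / reps + stats::var(two_step) / reps)
  expect_lt(abs(mean(one_pass) - mean(two_step)), 4 * se + 1e-6)
})
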