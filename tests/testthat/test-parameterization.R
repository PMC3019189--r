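# a minimal flat scheme: one transition row with an optional fixed End
# probability, used to exercise the update rule in isolation
tiny_pz <- function(end_prob = 0) {
  states <- c("Start", "s1", "End")
  alphabet <- c("a", "b")
  has_end_fixed <- end_prob > 0
  params <- dplyr::bind_rows(
    param_row("t_start", "fixed", NA, "trans", 1),
    param_row("p1", "free", "row", "trans", NA),
    param_row("p2", "free", "row", "trans", NA),
    if (has_end_fixed) param_row("t_end", "fixed", NA, "trans", end_prob),
    param_row("e_a", "free", "emit", "emit", 0.5),
    param_row("e_b", "derived", "emit", "emit", 0.5)
  )
  blocks <- tibble::tibble(block = c("row", "emit"), mass = c(1 - end_prob, 1))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", "s1", list("t_start")),
    entry_rows("trans", "s1", "s1", list("p1")),
    entry_rows("trans", "s1", "End",
               if (has_end_fixed) list("t_end") else list("p2")),
    entry_rows("emit", "s1", c("a", "b"), list("e_a", "e_b"))
  )
  hmm_parameterization(entries, params, blocks, states, alphabet)
}

test_that("the pseudocount update normalizes counts within each block", {
  pz <- tiny_pz()
  # counts 2 and 6 with pseudocount 1 -> (2+1)/10 and (6+1)/10
  v <- update_parameters(c(p1 = 2, p2 = 6, e_a = 0, e_b = 0, t_start = 0),
                         pz, pseudocount = 1)
  expect_equal(unname(v[c("p1", "p2")]), c(0.3, 0.7))
  # all-zero counts fall back to the uniform pseudocount solution
  expect_equal(unname(v[c("e_a", "e_b")]), c(0.5, 0.5))
  # fixed parameters are untouched
  expect_equal(unname(v["t_start"]), 1)
})

test_that("fixed entries keep their mass and the remainder is split by counts", {
  states <- c("Start", "s1", "End")
  params <- dplyr::bind_rows(
    param_row("t_start", "fixed", NA, "trans", 1),
    param_row("t_end", "fixed", NA, "trans", 0.1),
    param_row("q1", "free", "row", "trans", NA),
    param_row("q2", "free", "row", "trans", NA),
    param_row("e_a", "free", "emit", "emit", 1)
  )
  blocks <- tibble::tibble(block = c("row", "emit"), mass = c(0.9, 1))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", "s1", list("t_start")),
    entry_rows("trans", "s1", c("s1", "End"), list("q1", "t_end")),
    entry_rows("emit", "s1", "a", list("e_a"))
  )
  # q2 is tied into the same block but lives on no coordinate here; the
  # update only depends on the block structure
  pz <- hmm_parameterization(entries, params, blocks, states, "a")
  v <- update_parameters(c(q1 = 4, q2 = 4, e_a = 1, t_start = 0, t_end = 0),
                         pz, pseudocount = 0)
  expect_equal(unname(v[c("q1", "q2")]), c(0.45, 0.45))
})

test_that("a block with zero counts and zero pseudocount cannot normalize", {
  pz <- tiny_pz()
  expect_error(
    update_parameters(c(p1 = 0, p2 = 0, e_a = 1, e_b = 0, t_start = 0),
                      pz, pseudocount = 0),
    "cannot normalize")
})

test_that("random initialization is reproducible and respects block masses", {
  ex <- build_dishonest_casino()
  v1 <- random_initialize(ex$parameterization, seed = 11)
  v2 <- random_initialize(ex$parameterization, seed = 11)
  v3 <- random_initialize(ex$parameterization, seed = 12)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  m <- apply_parameters(ex$model, ex$parameterization, v1)
  expect_equal(nrow(validate_model(m)), 0L)
  # fixed parameters never move
  expect_equal(unname(v1["t_end"]), 2 / 5000)
})

test_that("initial draws in a constrained block stay inside the remaining simplex", {
  pz <- tiny_pz(end_prob = 0.9)
  for (s in 1:25) {
    v <- random_initialize(pz, seed = s)
    expect_gt(v[["p1"]], 0)
    expect_lt(v[["p1"]], 0.1)
    expect_equal(v[["p1"]] + v[["p2"]], 0.1)
  }
})

test_that("flat simplex draws have the expected first moment", {
  pz <- tiny_pz()
  draws <- with_seed_test(99, replicate(10000, {
    g <- rexp(2)
    (g / sum(g))[1]
  }))
  # oracle moments of the flat 2-simplex: mean 1/2, var 1/12
  se <- sqrt(1 / 12 / length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  vals <- sapply(1:2000, function(s) random_initialize(pz, seed = s)[["p1"]])
  se2 <- sqrt(1 / 12 / length(vals))
  expect_lt(abs(mean(vals) - 0.5), 4 * se2)
})

test_that("tied coordinates pool their counts onto one parameter", {
  ex <- build_extended_casino()
  cnt <- zero_counts_test(ex$model)
  cnt$emit["F1", "3"] <- 2
  cnt$emit["F2", "3"] <- 5
  agg <- aggregate_counts(cnt, ex$parameterization)
  expect_equal(agg$count[agg$param == "e_F_3"], 7)
  # empty counts pool to zero everywhere
  agg0 <- aggregate_counts(zero_counts_test(ex$model), ex$parameterization)
  expect_true(all(agg0$count == 0))
})

test_that("count pooling conserves mass for one-factor (flat) schemes", {
  for (builder in list(build_dishonest_casino, build_extended_casino, build_toy2)) {
    ex <- builder()
    cnt <- zero_counts_test(ex$model)
    set.seed(4)
    cnt$trans[ex$model$trans > 0] <- rpois(sum(ex$model$trans > 0), 5)
    cnt$emit[ex$model$emit > 0] <- rpois(sum(ex$model$emit > 0), 5)
    agg <- aggregate_counts(cnt, ex$parameterization)
    expect_equal(sum(agg$count), sum(cnt$trans) + sum(cnt$emit))
  }
})

test_that("updated parameters always rebuild a valid model", {
  for (builder in list(build_dishonest_casino, build_extended_casino,
                       build_cpg_model, build_toy2)) {
    ex <- builder()
    set.seed(7)
    for (rep in 1:5) {
      cnt <- zero_counts_test(ex$model)
      cnt$trans[ex$model$trans > 0] <- rpois(sum(ex$model$trans > 0), 20)
      cnt$emit[ex$model$emit > 0] <- rpois(sum(ex$model$emit > 0), 20)
      v <- update_parameters(setNames(aggregate_counts(cnt, ex$parameterization)$count,
                                      aggregate_counts(cnt, ex$parameterization)$param),
                             ex$parameterization, pseudocount = 1)
      m <- apply_parameters(ex$model, ex$parameterization, v)
      expect_equal(nrow(validate_model(m)), 0L)
    }
  }
})
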