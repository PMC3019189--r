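#' Forward algorithm (full matrix)
#'
#' Computes the scaled forward matrix and the sequence log-likelihood
#' log P(X). The matrix can be reused to sample any number of posterior
#' paths with [sample_posterior_paths()] without recomputation.
#'
#' @inheritParams viterbi_decode
#' @return List of class `hmm_forward`: `fhat` (per-position scaled
#'   forward values, states x (L+1)), `logscale` (per-position log scale
#'   factors) and `log_prob` = log P(X).
#' @export
forward_probability <- function(model, symbols) {
  obs <- encode_symbols(model, symbols)
  res <- .cpp_forward(model$trans, model$emit, obs)
  dimnames(res$fhat) <- list(model$states, NULL)
  res$symbols <- obs
  class(res) <- "hmm_forward"
  res
}

#' @export
print.hmm_forward <- function(x, ...) {
  cat(sprintf("<hmm_forward> L = %d, log P(X) = %.6g\n",
              ncol(x$fhat) - 1L, x$log_prob))
  invisible(x)
}

#' Sample state paths by stochastic back-tracing (two-step)
#'
#' Starting at the End state, repeatedly samples the previous state with
#' probability proportional to the forward value times the transition
#' probability into the current state (the emission term is constant over
#' candidates and the per-position scale factors cancel). Each returned
#' path is an exact draw from the posterior P(path | X).
#'
#' @param model An [hmm_model()].
#' @param forward An `hmm_forward` object from [forward_probability()].
#' @param n Number of independent paths to sample.
#' @return A list of `n` character vectors of emitting states.
#' @export
sample_posterior_paths <- function(model, forward, n = 1L) {
  paths <- .cpp_sample_paths(model$trans, model$emit, forward$symbols,
                             forward$fhat, as.integer(n))
  lapply(seq_len(nrow(paths)), function(i) model$states[paths[i, ]])
}

#' One-pass, linear-memory sampling counts for stochastic EM
#'
#' Runs the forward recursion once and, at every position and state,
#' samples a previous state from the back-tracing distribution for each of
#' `k` independent chains, propagating per-state cumulative count tables.
#' The End-state draw at termination selects each chain's final tables,
#' which are distributed exactly as the transition/emission counts of a
#' path drawn from the posterior P(path | X). Retained memory is
#' independent of the sequence length; randomness is consumed at every
#' (position, reachable state, chain) triple, so the two-step sampler and
#' this one-pass algorithm agree in distribution, not draw for draw.
#'
#' @inheritParams viterbi_decode
#' @param k Number of independent sampled paths (chains).
#' @return List of class `hmm_sem_counts`: `counts` (list of `k`
#'   `hmm_counts` objects), `log_prob` = log P(X) and `retained_doubles`.
#' @export
sem_counts <- function(model, symbols, k = 1L) {
  obs <- encode_symbols(model, symbols)
  res <- .cpp_sem_counts(model$trans, model$emit, obs, as.integer(k))
  counts <- lapply(seq_len(k), function(c) {
    tr <- res$trans_counts[[c]]
    em <- res$emit_counts[[c]]
    dimnames(tr) <- list(model$states, model$states)
    dimnames(em) <- list(model$states, model$alphabet)
    new_hmm_counts(tr, em, res$log_prob)
  })
  structure(list(counts = counts, log_prob = res$log_prob,
                 retained_doubles = res$retained_doubles),
            class = "hmm_sem_counts")
}

#' @export
print.hmm_sem_counts <- function(x, ...) {
  cat(sprintf("<hmm_sem_counts> %d sampled chains, log P(X) = %.6g\n",
              length(x$counts), x$log_prob))
  invisible(x)
}
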