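#' Posterior-expected transition and emission counts
#'
#' The Baum-Welch E-step for one sequence: real-valued expected counts of
#' every transition and emission over all state paths, weighted by their
#' posterior probability.
#'
#' Two engines are available. `"forward-backward"` is the classical
#' two-pass procedure over stored matrices. `"linear"` is a one-pass,
#' sequence-length-independent-memory recursion that propagates, for every
#' current state, the expected count tables conditional on occupying that
#' state, mixed over predecessors with their posterior weights; it is
#' implemented to an equivalence contract against the two-pass engine.
#'
#' @inheritParams viterbi_decode
#' @param engine `"linear"` (default) or `"forward-backward"`.
#' @return An `hmm_counts` object with real-valued matrices and
#'   `log_prob` = log P(X); the linear engine also reports
#'   `retained_doubles`.
#' @export
expected_counts <- function(model, symbols, engine = c("linear", "forward-backward")) {
  engine <- match.arg(engine)
  obs <- encode_symbols(model, symbols)
  res <- if (engine == "linear") {
    .cpp_expected_counts_linear(model$trans, model$emit, obs)
  } else {
    .cpp_expected_counts_fb(model$trans, model$emit, obs)
  }
  dimnames(res$trans_counts) <- list(model$states, model$states)
  dimnames(res$emit_counts) <- list(model$states, model$alphabet)
  extra <- if (engine == "linear") list(retained_doubles = res$retained_doubles) else list()
  new_hmm_counts(res$trans_counts, res$emit_counts, res$log_prob, extra = extra)
}
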