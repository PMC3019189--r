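#' Viterbi decoding with traceback (two-step)
#'
#' Computes the full dynamic-programming matrix in log space and recovers
#' an optimal Start-to-End state path by traceback. Ties in the argmax are
#' broken toward the lowest previous-state index, identically to the
#' one-pass counting algorithm, so the two procedures always agree on the
#' path.
#'
#' @param model An [hmm_model()].
#' @param symbols Sequence string or character vector over the model
#'   alphabet (length >= 1).
#' @return A list of class `hmm_path` with `states` (the L emitting
#'   states), `labels` (label-code string) and `log_prob`, the log joint
#'   probability of the sequence and the optimal path.
#' @export
viterbi_decode <- function(model, symbols) {
  obs <- encode_symbols(model, symbols)
  res <- .cpp_viterbi_full(model$trans, model$emit, obs)
  states <- model$states[res$path]
  structure(
    list(states = states,
         labels = collapse_chr(model$state_labels[states]),
         log_prob = res$log_prob),
    class = "hmm_path"
  )
}

#' @export
print.hmm_path <- function(x, ...) {
  cat(sprintf("<hmm_path> L = %d, log P(X, path) = %.6g\n",
              length(x$states), x$log_prob))
  invisible(x)
}

#' One-pass, linear-memory Viterbi training counts
#'
#' Scans the sequence once, left to right, carrying for every state the
#' cumulative transition and emission counts of the best path ending there
#' alongside the Viterbi values of the previous position. At termination
#' the End state's tables are exactly the transition/emission counts of
#' the Viterbi path, and the returned log-probability is the path's log
#' joint probability, without ever materializing the path or the matrix.
#' Retained memory is independent of the sequence length.
#'
#' @inheritParams viterbi_decode
#' @return An `hmm_counts` object with integer-valued count matrices,
#'   `log_prob`, a rolling `path_hash` of the implied traceback path (used
#'   for strict path-identity convergence checks) and `retained_doubles`,
#'   the instrumented size of the rolling DP state.
#' @export
viterbi_counts <- function(model, symbols) {
  obs <- encode_symbols(model, symbols)
  res <- .cpp_viterbi_counts(model$trans, model$emit, obs)
  dimnames(res$trans_counts) <- list(model$states, model$states)
  dimnames(res$emit_counts) <- list(model$states, model$alphabet)
  new_hmm_counts(res$trans_counts, res$emit_counts, res$log_prob,
                 extra = list(path_hash = res$path_hash,
                              retained_doubles = res$retained_doubles))
}
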