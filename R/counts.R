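# Count-vector container shared by all training algorithms.

new_hmm_counts <- function(trans, emit, log_prob = NA_real_, extra = list()) {
  structure(c(list(trans = trans, emit = emit, log_prob = log_prob), extra),
            class = "hmm_counts")
}

#' @export
print.hmm_counts <- function(x, ...) {
  cat(sprintf("<hmm_counts> %g transitions, %g emissions, log P = %.6g\n",
              sum(x$trans), sum(x$emit), x$log_prob))
  invisible(x)
}

#' @method tidy hmm_counts
#' @export
tidy.hmm_counts <- function(x, ...) {
  tr <- as.data.frame.table(x$trans, responseName = "count", stringsAsFactors = FALSE)
  names(tr) <- c("state", "target", "count")
  em <- as.data.frame.table(x$emit, responseName = "count", stringsAsFactors = FALSE)
  names(em) <- c("state", "target", "count")
  dplyr::filter(
    dplyr::bind_rows(trans = as_tibble(tr), emit = as_tibble(em), .id = "kind"),
    .data$count != 0
  )
}

sum_counts <- function(a, b) {
  new_hmm_counts(a$trans + b$trans, a$emit + b$emit,
                 log_prob = a$log_prob + b$log_prob)
}

zero_counts <- function(model) {
  S <- length(model$states)
  A <- length(model$alphabet)
  new_hmm_counts(
    matrix(0, S, S, dimnames = list(model$states, model$states)),
    matrix(0, S, A, dimnames = list(model$states, model$alphabet)),
    log_prob = 0
  )
}

#' Count transitions and emissions along an explicit state path
#'
#' The reference way to obtain training counts from a materialized path
#' (Viterbi traceback or a sampled path): one transition per consecutive
#' state pair of the complete Start -> ... -> End path and one emission per
#' position. For an L-symbol sequence the transition counts total L + 1 and
#' the emission counts total L.
#'
#' @param model An [hmm_model()].
#' @param states Character vector of the L emitting states, in order.
#' @param symbols Sequence string or character vector of the L symbols.
#' @return An `hmm_counts` object (without a log-probability).
#' @export
path_counts <- function(model, states, symbols) {
  cnt <- zero_counts(model)
  cnt$log_prob <- NA_real_
  sym <- model$alphabet[encode_symbols(model, symbols)]
  stopifnot(length(states) == length(sym))
  full <- c("Start", states, "End")
  for (k in seq_along(states)) {
    cnt$trans[full[k], full[k + 1L]] <- cnt$trans[full[k], full[k + 1L]] + 1
    cnt$emit[states[k], sym[k]] <- cnt$emit[states[k], sym[k]] + 1
  }
  cnt$trans[full[length(states) + 1L], "End"] <-
    cnt$trans[full[length(states) + 1L], "End"] + 1
  cnt
}

# log joint probability of a complete path + sequence
path_log_prob <- function(model, states, symbols) {
  sym <- encode_symbols(model, symbols)
  full <- c("Start", states, "End")
  lp <- 0
  for (k in seq_along(states)) {
    lp <- lp + log(model$trans[full[k], full[k + 1L]]) +
      log(model$emit[states[k], sym[k]])
  }
  lp + log(model$trans[full[length(sym) + 1L], "End"])
}
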