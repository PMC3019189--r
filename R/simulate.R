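#' Simulate one sequence by ancestral sampling
#'
#' Follows transitions from `Start`, emitting one symbol per non-silent
#' state, until the `End` state is reached. Draws whose paths exceed
#' `max_length` symbols before reaching `End` are rejected and redrawn up
#' to `retries` times.
#'
#' @param model An [hmm_model()].
#' @param max_length Maximum number of emitted symbols per draw.
#' @param retries How many rejected draws to tolerate before erroring.
#' @return A list with `sequence` (string), `states` (character vector of
#'   emitting states) and `labels` (string of per-position label codes).
#' @export
simulate_sequence <- function(model, max_length = 100000L, retries = 100L) {
  for (i in seq_len(retries)) {
    draw <- .cpp_simulate_path(model$trans, model$emit, as.integer(max_length))
    if (draw$complete) {
      states <- model$states[draw$states]
      return(list(
        sequence = collapse_chr(model$alphabet[draw$symbols]),
        states = states,
        labels = collapse_chr(model$state_labels[states])
      ))
    }
  }
  stop(sprintf("End state not reached within %d symbols in %d attempts; is End reachable?",
               max_length, retries))
}

# Backward length-feasibility recursion: column r (1-based r+1) holds
# u_i(r) = P(End is reached after emitting exactly r more symbols | state i),
# column-normalized to avoid underflow (only ratios are used).
length_feasibility <- function(model, length) {
  S <- length(model$states)
  em <- seq.int(2L, S - 1L)
  U <- matrix(0, S, length)
  U[em, 1L] <- model$trans[em, S]
  if (length >= 2L) {
    Tee <- model$trans[em, em, drop = FALSE]
    for (r in seq.int(2L, length)) {
      col <- Tee %*% U[em, r - 1L]
      mx <- max(col)
      if (mx <= 0) stop(sprintf("no path of length %d exists in this model", r))
      U[em, r] <- col / mx
    }
  }
  U
}

#' Generate a fixed-length labeled dataset
#'
#' Samples `n` state paths of exactly `length` emitting positions from the
#' model's conditional path distribution given total length, then emits
#' symbols. Conditioning is exact: transition choices are reweighted by the
#' probability that the remaining path reaches `End` after exactly the
#' remaining number of symbols, so the sampled paths follow the model's
#' distribution conditioned on the target length.
#'
#' @param x An [hmm_model()] or an example-model list holding `$model`.
#' @param n Number of sequences.
#' @param length Emitted symbols per sequence.
#' @param seed Root seed; each sequence uses a derived child seed so the
#'   dataset is reproducible record by record.
#' @return Tibble with columns `id`, `sequence`, `labels` and attribute
#'   `metadata` (model name, seed, length).
#' @seealso [write_dataset()], [read_sequences()]
#' @export
generate_dataset <- function(x, n, length, seed = NULL) {
  model <- if (inherits(x, "hmm_model")) x else x$model
  stopifnot(n >= 1L, length >= 1L)
  U <- length_feasibility(model, length)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (is.null(seed)) NULL else child_seed(seed, "simulate", i)
    draw <- with_seed(s, .cpp_simulate_conditional(model$trans, model$emit, U))
    states <- model$states[draw$states]
    rows[[i]] <- tibble(
      id = sprintf("seq%04d", i),
      sequence = collapse_chr(model$alphabet[draw$symbols]),
      labels = collapse_chr(model$state_labels[states])
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- list(
    model = if (inherits(x, "hmm_model")) "custom" else x$name %||% "custom",
    n = n, length = length, seed = seed
  )
  out
}
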