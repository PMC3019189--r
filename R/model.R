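#' Construct a hidden Markov model
#'
#' A first-order HMM over a finite alphabet, with two silent states: the
#' first state (`Start`) and the last (`End`). All other states emit one
#' symbol per visit. Transition and emission probabilities are stored in
#' linear space; the dynamic-programming routines convert to log space or
#' use per-position scaling as appropriate.
#'
#' @param states Character vector of state names; the first must be
#'   `"Start"` and the last `"End"`.
#' @param alphabet Character vector of single-character symbols.
#' @param trans Square numeric matrix of transition probabilities,
#'   `trans[i, j] = P(next = j | current = i)`, indexed like `states`.
#' @param emit Numeric matrix with one row per state (silent rows all zero)
#'   and one column per alphabet symbol.
#' @param state_labels Optional named character vector assigning each
#'   emitting state a single-character label code used in label files and
#'   per-position evaluation (defaults to the first character of the state
#'   name).
#'
#' @return An object of class `hmm_model`.
#' @seealso [validate_model()], [t_max()], [simulate_sequence()]
#' @export
hmm_model <- function(states, alphabet, trans, emit, state_labels = NULL) {
  states <- as.character(states)
  alphabet <- as.character(alphabet)
  S <- length(states)
  stopifnot(S >= 3L, states[1L] == "Start", states[S] == "End",
            !anyDuplicated(states), !anyDuplicated(alphabet),
            all(nchar(alphabet) == 1L),
            is.matrix(trans), nrow(trans) == S, ncol(trans) == S,
            is.matrix(emit), nrow(emit) == S, ncol(emit) == length(alphabet))
  dimnames(trans) <- list(states, states)
  dimnames(emit) <- list(states, alphabet)
  emitting <- states[-c(1L, S)]
  if (is.null(state_labels)) {
    state_labels <- setNames(substr(emitting, 1L, 1L), emitting)
  }
  stopifnot(setequal(names(state_labels), emitting))
  structure(
    list(states = states, alphabet = alphabet, trans = trans, emit = emit,
         state_labels = state_labels[emitting]),
    class = "hmm_model"
  )
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states (%d emitting), alphabet {%s}\n",
              length(x$states), length(x$states) - 2L,
              paste(x$alphabet, collapse = ",")))
  cat(sprintf("  %d structural transitions, %d structural emissions, T_max = %d\n",
              sum(x$trans > 0), sum(x$emit > 0), t_max(x)))
  invisible(x)
}

emitting_states <- function(model) {
  model$states[-c(1L, length(model$states))]
}

#' Model connectivity
#'
#' The maximum number of states any state is connected to (the larger of the
#' maximum out-degree and in-degree over the structural transition support).
#'
#' @param model An [hmm_model()].
#' @return Integer scalar.
#' @export
t_max <- function(model) {
  max(max(rowSums(model$trans > 0)), max(colSums(model$trans > 0)))
}

#' Validate an HMM's probability tables and topology
#'
#' Reports violations instead of throwing: each row of the result names the
#' offending coordinate and the rule it breaks. An empty tibble means the
#' model satisfies all invariants: rows of the transition matrix sum to one
#' for every state with outgoing transitions, emission rows of emitting
#' states sum to one, no transitions enter `Start` or leave `End`, the
#' silent states emit nothing, and no probability is negative.
#'
#' @param model An [hmm_model()].
#' @param tol Numeric tolerance for the row-sum checks.
#' @return A tibble with columns `coordinate` and `rule` (zero rows when
#'   valid).
#' @export
validate_model <- function(model, tol = 1e-9) {
  S <- length(model$states)
  viol <- list()
  add <- function(coordinate, rule) {
    viol[[length(viol) + 1L]] <<- tibble(coordinate = coordinate, rule = rule)
  }
  if (any(model$trans < 0)) {
    bad <- which(model$trans < 0, arr.ind = TRUE)[1L, ]
    add(sprintf("t[%s,%s]", model$states[bad[1L]], model$states[bad[2L]]),
        "negative transition probability")
  }
  if (any(model$emit < 0)) {
    bad <- which(model$emit < 0, arr.ind = TRUE)[1L, ]
    add(sprintf("e[%s](%s)", model$states[bad[1L]], model$alphabet[bad[2L]]),
        "negative emission probability")
  }
  rs <- rowSums(model$trans)
  for (i in seq_len(S)) {
    if (rs[i] > 0 && abs(rs[i] - 1) > tol) {
      add(sprintf("t[%s,.]", model$states[i]),
          sprintf("transition row sums to %.6g, expected 1", rs[i]))
    }
  }
  es <- rowSums(model$emit)
  for (i in setdiff(seq_len(S), c(1L, S))) {
    if (abs(es[i] - 1) > tol) {
      add(sprintf("e[%s](.)", model$states[i]),
          sprintf("emission row sums to %.6g, expected 1", es[i]))
    }
  }
  if (any(model$trans[, 1L] > 0)) {
    j <- which(model$trans[, 1L] > 0)[1L]
    add(sprintf("t[%s,Start]", model$states[j]), "transition into Start state")
  }
  if (any(model$trans[S, ] > 0)) {
    j <- which(model$trans[S, ] > 0)[1L]
    add(sprintf("t[End,%s]", model$states[j]), "transition out of End state")
  }
  if (any(model$emit[c(1L, S), ] > 0)) {
    add("e[Start/End](.)", "silent state has emission probability")
  }
  if (length(viol) == 0L) {
    tibble(coordinate = character(), rule = character())
  } else {
    dplyr::bind_rows(viol)
  }
}
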