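#' Declare which probabilities of an HMM are trainable, tied, or fixed
#'
#' A parameterization factorizes every structural probability coordinate of
#' a model (a transition `t[state, target]` or an emission
#' `e[state](symbol)`) into a product of named parameters. Parameters are
#' organized into *simplex blocks*: the values of a block's parameters sum
#' to the block's `mass` (the probability left over in a normalization
#' group after fixed entries are removed). Each parameter carries a role:
#'
#' * `"free"` — an independent parameter adjusted by training,
#' * `"derived"` — determined by its block (it absorbs the remainder; its
#'   pooled counts enter the update denominator but it is not counted as an
#'   independent parameter),
#' * `"fixed"` — held constant at `value`, never trained, excluded from
#'   normalization.
#'
#' Tying is expressed by referencing the same parameter from several
#' coordinates; pooled counts are the sum over all coordinates that carry
#' the parameter as a factor. The common flat scheme (one parameter per
#' coordinate) is the one-factor special case; two-factor entries express
#' nested schemes such as a block-switch probability multiplied by a
#' destination-row distribution.
#'
#' @param entries Tibble with columns `kind` (`"trans"` or `"emit"`),
#'   `state`, `target` (target state or symbol) and `factors` (list column
#'   of character vectors of parameter names). Every structural coordinate
#'   must appear exactly once.
#' @param params Tibble with columns `param`, `role`, `block` (`NA` for
#'   fixed parameters), `kind` (`"trans"`/`"emit"`, used by convergence
#'   metrics) and `value` (constant for fixed parameters, `NA` otherwise).
#' @param blocks Tibble with columns `block` and `mass`.
#' @param states,alphabet State and symbol names of the model the scheme
#'   refers to.
#'
#' @return An object of class `hmm_parameterization`.
#' @export
hmm_parameterization <- function(entries, params, blocks, states, alphabet) {
  entries <- as_tibble(entries)
  params <- as_tibble(params)
  blocks <- as_tibble(blocks)
  stopifnot(all(c("kind", "state", "target", "factors") %in% names(entries)),
            all(c("param", "role", "block", "kind", "value") %in% names(params)),
            all(c("block", "mass") %in% names(blocks)),
            all(entries$kind %in% c("trans", "emit")),
            all(params$role %in% c("free", "fixed", "derived")),
            !anyDuplicated(params$param))
  used <- unique(unlist(entries$factors))
  missing <- setdiff(used, params$param)
  if (length(missing) > 0L) {
    stop("entries reference undeclared parameters: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(entries[c("kind", "state", "target")])) {
    stop("a probability coordinate appears more than once in the entries")
  }
  S <- length(states)
  A <- length(alphabet)
  # precomputed linear indices into c(trans, emit) for fast count pooling
  si <- match(entries$state, states)
  ti <- ifelse(entries$kind == "trans",
               match(entries$target, states),
               match(entries$target, alphabet))
  if (anyNA(si) || anyNA(ti)) stop("entry refers to an unknown state or symbol")
  coord <- ifelse(entries$kind == "trans",
                  si + S * (ti - 1L),
                  S * S + si + S * (ti - 1L))
  nf <- lengths(entries$factors)
  factor_entry <- rep(seq_len(nrow(entries)), nf)
  factor_param <- match(unlist(entries$factors), params$param)
  structure(
    list(entries = entries, params = params, blocks = blocks,
         states = states, alphabet = alphabet,
         coord = as.integer(coord),
         factor_entry = factor_entry, factor_param = factor_param),
    class = "hmm_parameterization"
  )
}

#' @export
print.hmm_parameterization <- function(x, ...) {
  cat(sprintf("<hmm_parameterization> %d coordinates, %d parameters (%d free, %d derived, %d fixed), %d blocks\n",
              nrow(x$entries), nrow(x$params),
              sum(x$params$role == "free"), sum(x$params$role == "derived"),
              sum(x$params$role == "fixed"), nrow(x$blocks)))
  invisible(x)
}

#' Number of independently trainable parameters
#' @param parameterization An [hmm_parameterization()].
#' @return Integer count of parameters with role `"free"`.
#' @export
n_free_parameters <- function(parameterization) {
  sum(parameterization$params$role == "free")
}

#' Rebuild a model's probability tables from parameter values
#'
#' Every structural coordinate is set to the product of its factor values;
#' coordinates outside the parameterization's support are zero.
#'
#' @param model Template [hmm_model()] supplying states, alphabet and label
#'   codes.
#' @param parameterization An [hmm_parameterization()].
#' @param values Named numeric vector covering all parameters (see
#'   [param_values()], [random_initialize()]).
#' @return A new `hmm_model`.
#' @export
apply_parameters <- function(model, parameterization, values) {
  pz <- parameterization
  miss <- setdiff(pz$params$param, names(values))
  if (length(miss) > 0L) stop("missing parameter values: ", paste(miss, collapse = ", "))
  S <- length(pz$states)
  A <- length(pz$alphabet)
  vals <- vapply(pz$entries$factors, function(f) prod(values[f]), numeric(1))
  flat <- numeric(S * S + S * A)
  flat[pz$coord] <- vals
  trans <- matrix(flat[seq_len(S * S)], S, S, dimnames = list(pz$states, pz$states))
  emit <- matrix(flat[S * S + seq_len(S * A)], S, A, dimnames = list(pz$states, pz$alphabet))
  hmm_model(pz$states, pz$alphabet, trans, emit, state_labels = model$state_labels)
}

#' Default parameter values of a parameterization
#'
#' Collects the fixed parameters' constants and the `value` column for free
#' and derived parameters when the builder supplied one.
#'
#' @param parameterization An [hmm_parameterization()].
#' @return Named numeric vector (NA for parameters without a stored value).
#' @export
param_values <- function(parameterization) {
  setNames(parameterization$params$value, parameterization$params$param)
}

#' Draw random initial parameter values
#'
#' Each simplex block's parameters are drawn jointly from the flat
#' (symmetric, concentration 1) distribution over the simplex scaled to the
#' block's mass — the probability left after fixed entries. Fixed
#' parameters keep their constants. Tied coordinates automatically receive
#' identical values because they reference the same parameter.
#'
#' @param parameterization An [hmm_parameterization()].
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Named numeric vector of parameter values.
#' @export
random_initialize <- function(parameterization, seed = NULL) {
  pz <- parameterization
  with_seed(seed, {
    values <- param_values(pz)
    for (b in seq_len(nrow(pz$blocks))) {
      name <- pz$blocks$block[b]
      mass <- pz$blocks$mass[b]
      if (mass <= 0) stop(sprintf("block '%s' has no probability mass left after fixed entries", name))
      members <- pz$params$param[!is.na(pz$params$block) & pz$params$block == name]
      if (length(members) == 1L) {
        values[members] <- mass
      } else {
        g <- rexp(length(members))
        values[members] <- mass * g / sum(g)
      }
    }
    values
  })
}

# Pool raw coordinate counts onto parameters: a parameter's count is the
# sum of counts over every coordinate that carries it as a factor.
# `counts` is a list with matrices `trans` (S x S) and `emit` (S x A).
param_counts_vector <- function(counts, parameterization) {
  pz <- parameterization
  flat <- c(counts$trans, counts$emit)
  entry_counts <- flat[pz$coord]
  out <- numeric(nrow(pz$params))
  agg <- tapply(entry_counts[pz$factor_entry], pz$factor_param, sum)
  out[as.integer(names(agg))] <- agg
  setNames(out, pz$params$param)
}

#' Pool raw transition/emission counts by parameter
#'
#' Tied coordinates contribute to the same parameter; fixed and derived
#' parameters' pooled counts are retained (derived counts enter the update
#' denominator, fixed counts are reported but never used).
#'
#' @param counts An `hmm_counts` object or a list with `trans` and `emit`
#'   count matrices.
#' @param parameterization An [hmm_parameterization()].
#' @return Tibble with columns `param`, `role`, `kind`, `block`, `count`.
#' @export
aggregate_counts <- function(counts, parameterization) {
  cnt <- param_counts_vector(counts, parameterization)
  dplyr::mutate(parameterization$params[c("param", "role", "kind", "block")],
                count = unname(cnt))
}

#' Re-estimate parameter values from pooled counts
#'
#' Within each simplex block, every parameter's new value is
#' `mass * (count + pseudocount) / sum(count + pseudocount)` over the
#' block's members — the count-normalization update shared by Viterbi,
#' stochastic EM and Baum-Welch training. Pseudocounts are added once per
#' block member (a tied parameter counts once, however many coordinates
#' pool into it). Fixed parameters are returned unchanged.
#'
#' @param counts Named numeric vector of pooled parameter counts (see
#'   [aggregate_counts()]) or the tibble returned by it.
#' @param parameterization An [hmm_parameterization()].
#' @param pseudocount Non-negative constant added to each member's count.
#' @return Named numeric vector of updated parameter values.
#' @export
update_parameters <- function(counts, parameterization, pseudocount = 1) {
  pz <- parameterization
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$param)
  stopifnot(pseudocount >= 0, all(counts >= 0, na.rm = TRUE))
  values <- param_values(pz)
  for (b in seq_len(nrow(pz$blocks))) {
    name <- pz$blocks$block[b]
    mass <- pz$blocks$mass[b]
    members <- pz$params$param[!is.na(pz$params$block) & pz$params$block == name]
    cnt <- counts[members] + pseudocount
    tot <- sum(cnt)
    if (tot <= 0) {
      stop(sprintf("cannot normalize block '%s': all counts and pseudocounts are zero", name))
    }
    values[members] <- mass * cnt / tot
  }
  values
}

#' Check a parameterization against a model
#'
#' Verifies that the entries cover exactly the model's structural support,
#' that every normalization group (a state's outgoing transitions, an
#' emitting state's emission row) sums to one, and that each block's
#' parameter values sum to its mass.
#'
#' @param parameterization An [hmm_parameterization()].
#' @param model An [hmm_model()] built from it.
#' @param values Named parameter values (defaults to the stored ones).
#' @param tol Tolerance for the sum checks.
#' @return Tibble of violations (zero rows when consistent).
#' @export
validate_parameterization <- function(parameterization, model,
                                      values = param_values(parameterization),
                                      tol = 1e-9) {
  pz <- parameterization
  viol <- list()
  add <- function(coordinate, rule) {
    viol[[length(viol) + 1L]] <<- tibble(coordinate = coordinate, rule = rule)
  }
  S <- length(pz$states)
  A <- length(pz$alphabet)
  support <- c(model$trans > 0, model$emit > 0)
  covered <- logical(S * S + S * A)
  covered[pz$coord] <- TRUE
  if (any(support & !covered)) add("entries", "structural coordinate missing from parameterization")
  for (b in seq_len(nrow(pz$blocks))) {
    members <- pz$params$param[!is.na(pz$params$block) & pz$params$block == pz$blocks$block[b]]
    s <- sum(values[members])
    if (is.finite(s) && abs(s - pz$blocks$mass[b]) > tol) {
      add(pz$blocks$block[b], sprintf("block sums to %.6g, expected mass %.6g", s, pz$blocks$mass[b]))
    }
  }
  mv <- validate_model(model, tol = tol)
  if (nrow(mv) > 0L) viol[[length(viol) + 1L]] <- mv
  if (length(viol) == 0L) tibble(coordinate = character(), rule = character())
  else dplyr::bind_rows(viol)
}
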