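# Built-in example models: the dishonest casino, an extended casino whose
# dice can only be used in fixed run lengths, a CpG-island model, and two
# tiny fixtures used throughout the tests.

entry_rows <- function(kind, state, target, factors) {
  tibble(kind = kind, state = state, target = target, factors = factors)
}

param_row <- function(param, role, block, kind, value = NA_real_) {
  tibble(param = param, role = role, block = block, kind = kind, value = value)
}

matrices_from_values <- function(pz, values) {
  S <- length(pz$states)
  A <- length(pz$alphabet)
  vals <- vapply(pz$entries$factors, function(f) prod(values[f]), numeric(1))
  flat <- numeric(S * S + S * A)
  flat[pz$coord] <- vals
  list(
    trans = matrix(flat[seq_len(S * S)], S, S, dimnames = list(pz$states, pz$states)),
    emit = matrix(flat[S * S + seq_len(S * A)], S, A, dimnames = list(pz$states, pz$alphabet))
  )
}

new_example <- function(name, pz, values, state_labels, positive_labels, symmetries = NULL) {
  mats <- matrices_from_values(pz, values)
  model <- hmm_model(pz$states, pz$alphabet, mats$trans, mats$emit, state_labels)
  structure(
    list(name = name, model = model, parameterization = pz,
         true_values = values, positive_labels = positive_labels,
         symmetries = symmetries),
    class = "hmm_example"
  )
}

#' @export
print.hmm_example <- function(x, ...) {
  cat(sprintf("<hmm_example> '%s': %d free parameters, positive labels {%s}\n",
              x$name, n_free_parameters(x$parameterization),
              paste(x$positive_labels, collapse = ",")))
  print(x$model)
  invisible(x)
}

#' The dishonest casino model
#'
#' A four-state HMM (silent Start/End plus a fair state F and a loaded
#' state L) over dice symbols 1-6, with 8 structural transitions and 12
#' structural emissions. The tying scheme trains 12 values: the two
#' switch probabilities F->L and L->F (the self-transitions are derived,
#' the Start and End transitions fixed) and five free emissions per dice
#' (the sixth face is derived).
#'
#' @param true_params Optional named list overriding the simulation
#'   defaults: `switch_FL`, `switch_LF`, `end_prob`, `emit_F`, `emit_L`
#'   (length-6 probability vectors).
#' @return An `hmm_example` list: `model`, `parameterization`,
#'   `true_values`, `positive_labels` (`"L"`), and the model's label
#'   `symmetries` (F and L may be exchanged without changing the law of
#'   the data; used by identifiability-aware convergence metrics).
#' @export
build_dishonest_casino <- function(true_params = list()) {
  p <- utils::modifyList(list(
    switch_FL = 0.05, switch_LF = 0.1, end_prob = 2 / 5000,
    emit_F = rep(1 / 6, 6), emit_L = c(rep(0.1, 5), 0.5)
  ), true_params)
  stopifnot(length(p$emit_F) == 6, abs(sum(p$emit_F) - 1) < 1e-9,
            length(p$emit_L) == 6, abs(sum(p$emit_L) - 1) < 1e-9,
            p$end_prob > 0, p$end_prob < 1,
            p$switch_FL > 0, p$switch_FL < 1 - p$end_prob,
            p$switch_LF > 0, p$switch_LF < 1 - p$end_prob)
  states <- c("Start", "F", "L", "End")
  alphabet <- as.character(1:6)
  mass <- 1 - p$end_prob

  params <- dplyr::bind_rows(
    param_row("t_start_F", "fixed", NA, "trans", 0.5),
    param_row("t_start_L", "fixed", NA, "trans", 0.5),
    param_row("t_end", "fixed", NA, "trans", p$end_prob),
    param_row("t_FL", "free", "trans_F", "trans", p$switch_FL),
    param_row("t_FF", "derived", "trans_F", "trans", mass - p$switch_FL),
    param_row("t_LF", "free", "trans_L", "trans", p$switch_LF),
    param_row("t_LL", "derived", "trans_L", "trans", mass - p$switch_LF),
    dplyr::bind_rows(lapply(1:6, function(y) {
      param_row(paste0("e_F_", y), if (y < 6) "free" else "derived",
                "emit_F", "emit", p$emit_F[y])
    })),
    dplyr::bind_rows(lapply(1:6, function(y) {
      param_row(paste0("e_L_", y), if (y < 6) "free" else "derived",
                "emit_L", "emit", p$emit_L[y])
    }))
  )
  blocks <- tibble(block = c("trans_F", "trans_L", "emit_F", "emit_L"),
                   mass = c(mass, mass, 1, 1))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", c("F", "L"), list("t_start_F", "t_start_L")),
    entry_rows("trans", "F", c("F", "L", "End"), list("t_FF", "t_FL", "t_end")),
    entry_rows("trans", "L", c("L", "F", "End"), list("t_LL", "t_LF", "t_end")),
    entry_rows("emit", "F", as.character(1:6), as.list(paste0("e_F_", 1:6))),
    entry_rows("emit", "L", as.character(1:6), as.list(paste0("e_L_", 1:6)))
  )
  pz <- hmm_parameterization(entries, params, blocks, states, alphabet)
  swap <- c(
    setNames("t_LF", "t_FL"), setNames("t_FL", "t_LF"),
    setNames(paste0("e_L_", 1:5), paste0("e_F_", 1:5)),
    setNames(paste0("e_F_", 1:5), paste0("e_L_", 1:5))
  )
  new_example("dishonest_casino", pz, param_values(pz),
              state_labels = c(F = "F", L = "L"),
              positive_labels = "L", symmetries = list(swap))
}

#' The extended dishonest casino model
#'
#' Seven states: silent Start/End, a fair dice that must be used in runs
#' of three (F1 -> F2 -> F3) and a loaded dice used in runs of two
#' (L1 -> L2), giving 11 structural transitions and 30 structural
#' emissions. The three F states share one fair emission distribution and
#' the two L states one loaded distribution, so 12 values are trained:
#' two switch probabilities (F3 -> L1, L2 -> F1; the return transitions
#' are derived, the chain and Start/End transitions fixed) plus 5 + 5
#' tied free emissions.
#'
#' @inheritParams build_dishonest_casino
#' @return An `hmm_example`; positive label `"L"`.
#' @export
build_extended_casino <- function(true_params = list()) {
  p <- utils::modifyList(list(
    switch_FL = 0.05, switch_LF = 0.1, end_prob = 2 / 5000,
    emit_F = rep(1 / 6, 6), emit_L = c(rep(0.1, 5), 0.5)
  ), true_params)
  states <- c("Start", "F1", "F2", "F3", "L1", "L2", "End")
  alphabet <- as.character(1:6)
  mass <- 1 - p$end_prob

  params <- dplyr::bind_rows(
    param_row("t_start_F", "fixed", NA, "trans", 0.5),
    param_row("t_start_L", "fixed", NA, "trans", 0.5),
    param_row("t_end", "fixed", NA, "trans", p$end_prob),
    param_row("t_chain", "fixed", NA, "trans", 1),
    param_row("t_FL", "free", "trans_F3", "trans", p$switch_FL),
    param_row("t_FF", "derived", "trans_F3", "trans", mass - p$switch_FL),
    param_row("t_LF", "free", "trans_L2", "trans", p$switch_LF),
    param_row("t_LL", "derived", "trans_L2", "trans", mass - p$switch_LF),
    dplyr::bind_rows(lapply(1:6, function(y) {
      param_row(paste0("e_F_", y), if (y < 6) "free" else "derived",
                "emit_F", "emit", p$emit_F[y])
    })),
    dplyr::bind_rows(lapply(1:6, function(y) {
      param_row(paste0("e_L_", y), if (y < 6) "free" else "derived",
                "emit_L", "emit", p$emit_L[y])
    }))
  )
  blocks <- tibble(block = c("trans_F3", "trans_L2", "emit_F", "emit_L"),
                   mass = c(mass, mass, 1, 1))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", c("F1", "L1"), list("t_start_F", "t_start_L")),
    entry_rows("trans", "F1", "F2", list("t_chain")),
    entry_rows("trans", "F2", "F3", list("t_chain")),
    entry_rows("trans", "F3", c("F1", "L1", "End"), list("t_FF", "t_FL", "t_end")),
    entry_rows("trans", "L1", "L2", list("t_chain")),
    entry_rows("trans", "L2", c("L1", "F1", "End"), list("t_LL", "t_LF", "t_end")),
    dplyr::bind_rows(lapply(c("F1", "F2", "F3"), function(s) {
      entry_rows("emit", s, as.character(1:6), as.list(paste0("e_F_", 1:6)))
    })),
    dplyr::bind_rows(lapply(c("L1", "L2"), function(s) {
      entry_rows("emit", s, as.character(1:6), as.list(paste0("e_L_", 1:6)))
    }))
  )
  pz <- hmm_parameterization(entries, params, blocks, states, alphabet)
  new_example("extended_casino", pz, param_values(pz),
              state_labels = c(F1 = "F", F2 = "F", F3 = "F", L1 = "L", L2 = "L"),
              positive_labels = "L", symmetries = NULL)
}

#' The CpG-island model
#'
#' Ten states: silent Start/End plus one state per nucleotide inside a
#' CpG island (A+, C+, G+, T+) and one per nucleotide outside (A-, C-,
#' G-, T-). Every emitting state is connected to every emitting state and
#' to Start/End, giving 80 structural transitions. Emissions are delta
#' functions (state X+/X- emits nucleotide X with probability 1) and are
#' never trained.
#'
#' The transition tying scheme is nested: a shared, fixed End probability;
#' one free block-switch probability per direction (+ to -, - to +); one
#' next-base conditional distribution per source base inside each block
#' (3 free values per row), with cross-block transitions reusing the
#' destination block's row for the source base; and a 7-free-parameter
#' Start distribution — 33 free parameters in total.
#'
#' @param true_params Optional named list overriding defaults:
#'   `switch_pm`, `switch_mp`, `end_prob`, `within_plus` / `within_minus`
#'   (4x4 row-stochastic next-base matrices, rows/cols in A,C,G,T order)
#'   and `start` (length-8 probability vector over A+,C+,G+,T+,A-,C-,G-,T-).
#' @return An `hmm_example`; positive label `"+"`.
#' @export
build_cpg_model <- function(true_params = list()) {
  # CpG-enriched (+) and CpG-depleted (-) next-base conditionals; the
  # classic illustrative values for island vs background dinucleotide
  # structure.
  within_plus <- matrix(c(
    0.180, 0.274, 0.426, 0.120,
    0.171, 0.368, 0.274, 0.188,
    0.161, 0.339, 0.375, 0.125,
    0.079, 0.355, 0.384, 0.182), 4, 4, byrow = TRUE)
  within_minus <- matrix(c(
    0.300, 0.205, 0.285, 0.210,
    0.322, 0.298, 0.078, 0.302,
    0.248, 0.246, 0.298, 0.208,
    0.177, 0.239, 0.292, 0.292), 4, 4, byrow = TRUE)
  p <- utils::modifyList(list(
    switch_pm = 0.005, switch_mp = 0.0025, end_prob = 2 / 5000,
    within_plus = within_plus, within_minus = within_minus,
    start = c(rep(0.005, 4), rep(0.245, 4))
  ), true_params)
  nt <- c("A", "C", "G", "T")
  plus <- paste0(nt, "+")
  minus <- paste0(nt, "-")
  states <- c("Start", plus, minus, "End")
  mass <- 1 - p$end_prob
  # normalize the within-block rows defensively (printed values round)
  wp <- p$within_plus / rowSums(p$within_plus)
  wm <- p$within_minus / rowSums(p$within_minus)
  start <- p$start / sum(p$start)

  row_params <- function(prefix, mat) {
    dplyr::bind_rows(lapply(1:4, function(i) {
      dplyr::bind_rows(lapply(1:4, function(j) {
        param_row(sprintf("%s_%s_%s", prefix, nt[i], nt[j]),
                  if (j < 4) "free" else "derived",
                  sprintf("%s_%s", prefix, nt[i]), "trans", mat[i, j])
      }))
    }))
  }
  start_names <- c(paste0("start_", nt, "p"), paste0("start_", nt, "m"))
  params <- dplyr::bind_rows(
    param_row("t_end", "fixed", NA, "trans", p$end_prob),
    param_row("emit_one", "fixed", NA, "emit", 1),
    param_row("sw_pm", "free", "switch_plus", "trans", p$switch_pm),
    param_row("stay_p", "derived", "switch_plus", "trans", mass - p$switch_pm),
    param_row("sw_mp", "free", "switch_minus", "trans", p$switch_mp),
    param_row("stay_m", "derived", "switch_minus", "trans", mass - p$switch_mp),
    row_params("pp", wp),
    row_params("pm", wm),
    dplyr::bind_rows(lapply(1:8, function(i) {
      param_row(start_names[i], if (i < 8) "free" else "derived",
                "start", "trans", start[i])
    }))
  )
  blocks <- tibble(
    block = c("switch_plus", "switch_minus",
              paste0("pp_", nt), paste0("pm_", nt), "start"),
    mass = c(mass, mass, rep(1, 8), 1)
  )
  within_entries <- function(src_states, stay_param, pfx) {
    dplyr::bind_rows(lapply(1:4, function(i) {
      entry_rows("trans", src_states[i], src_states,
                 lapply(1:4, function(j) c(stay_param, sprintf("%s_%s_%s", pfx, nt[i], nt[j]))))
    }))
  }
  cross_entries <- function(src_states, dst_states, sw_param, pfx) {
    dplyr::bind_rows(lapply(1:4, function(i) {
      entry_rows("trans", src_states[i], dst_states,
                 lapply(1:4, function(j) c(sw_param, sprintf("%s_%s_%s", pfx, nt[i], nt[j]))))
    }))
  }
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", c(plus, minus), as.list(start_names)),
    within_entries(plus, "stay_p", "pp"),
    cross_entries(plus, minus, "sw_pm", "pm"),
    within_entries(minus, "stay_m", "pm"),
    cross_entries(minus, plus, "sw_mp", "pp"),
    entry_rows("trans", c(plus, minus), rep("End", 8),
               rep(list("t_end"), 8)),
    entry_rows("emit", c(plus, minus), rep(nt, 2), rep(list("emit_one"), 8))
  )
  pz <- hmm_parameterization(entries, params, blocks, states, nt)
  pp_names <- as.vector(outer(nt, nt[1:3], function(i, j) sprintf("pp_%s_%s", i, j)))
  pm_names <- sub("^pp", "pm", pp_names)
  swap <- c(
    setNames("sw_mp", "sw_pm"), setNames("sw_pm", "sw_mp"),
    setNames(pm_names, pp_names), setNames(pp_names, pm_names),
    setNames(paste0("start_", nt, "m"), paste0("start_", nt, "p")),
    setNames(paste0("start_", nt, "p")[1:3], paste0("start_", nt, "m")[1:3])
  )
  labels <- setNames(c(rep("+", 4), rep("-", 4)), c(plus, minus))
  new_example("cpg_island", pz, param_values(pz),
              state_labels = labels, positive_labels = "+",
              symmetries = list(swap))
}

#' Tiny fixture models
#'
#' `build_toy1()`: one emitting state S over alphabet \{A, B\} with
#' t(Start,S) = 1, t(S,S) = 0.6, t(S,End) = 0.4 and uniform emissions —
#' every sequence has exactly one possible path, so posterior quantities
#' are point masses. `build_toy2()`: two emitting states A, B over
#' \{H, T\} with fully trainable transitions and emissions and enumerable
#' path sets (2^L paths for length L).
#'
#' @return An `hmm_example`.
#' @export
build_toy1 <- function() {
  states <- c("Start", "S", "End")
  alphabet <- c("A", "B")
  params <- dplyr::bind_rows(
    param_row("t_start_S", "fixed", NA, "trans", 1),
    param_row("t_SS", "free", "trans_S", "trans", 0.6),
    param_row("t_S_end", "derived", "trans_S", "trans", 0.4),
    param_row("e_S_A", "free", "emit_S", "emit", 0.5),
    param_row("e_S_B", "derived", "emit_S", "emit", 0.5)
  )
  blocks <- tibble(block = c("trans_S", "emit_S"), mass = c(1, 1))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", "S", list("t_start_S")),
    entry_rows("trans", "S", c("S", "End"), list("t_SS", "t_S_end")),
    entry_rows("emit", "S", c("A", "B"), list("e_S_A", "e_S_B"))
  )
  pz <- hmm_parameterization(entries, params, blocks, states, alphabet)
  new_example("toy1", pz, param_values(pz), state_labels = c(S = "S"),
              positive_labels = "S")
}

#' @rdname build_toy1
#' @export
build_toy2 <- function() {
  states <- c("Start", "A", "B", "End")
  alphabet <- c("H", "T")
  params <- dplyr::bind_rows(
    param_row("t_start_A", "free", "start", "trans", 0.6),
    param_row("t_start_B", "derived", "start", "trans", 0.4),
    param_row("t_AA", "free", "trans_A", "trans", 0.5),
    param_row("t_AB", "free", "trans_A", "trans", 0.3),
    param_row("t_A_end", "derived", "trans_A", "trans", 0.2),
    param_row("t_BA", "free", "trans_B", "trans", 0.3),
    param_row("t_BB", "free", "trans_B", "trans", 0.5),
    param_row("t_B_end", "derived", "trans_B", "trans", 0.2),
    param_row("e_A_H", "free", "emit_A", "emit", 0.8),
    param_row("e_A_T", "derived", "emit_A", "emit", 0.2),
    param_row("e_B_H", "free", "emit_B", "emit", 0.3),
    param_row("e_B_T", "derived", "emit_B", "emit", 0.7)
  )
  blocks <- tibble(block = c("start", "trans_A", "trans_B", "emit_A", "emit_B"),
                   mass = rep(1, 5))
  entries <- dplyr::bind_rows(
    entry_rows("trans", "Start", c("A", "B"), list("t_start_A", "t_start_B")),
    entry_rows("trans", "A", c("A", "B", "End"), list("t_AA", "t_AB", "t_A_end")),
    entry_rows("trans", "B", c("A", "B", "End"), list("t_BA", "t_BB", "t_B_end")),
    entry_rows("emit", "A", c("H", "T"), list("e_A_H", "e_A_T")),
    entry_rows("emit", "B", c("H", "T"), list("e_B_H", "e_B_T"))
  )
  pz <- hmm_parameterization(entries, params, blocks, states, alphabet)
  new_example("toy2", pz, param_values(pz), state_labels = c(A = "A", B = "B"),
              positive_labels = "A")
}

#' Look up a built-in example model by name
#'
#' @param name One of `"dishonest-casino"`, `"extended-casino"`, `"cpg"`,
#'   `"toy1"`, `"toy2"` (underscores accepted).
#' @param true_params Passed through to the builder.
#' @return An `hmm_example`.
#' @export
build_example <- function(name, true_params = list()) {
  key <- gsub("_", "-", tolower(name))
  switch(key,
    "dishonest-casino" = build_dishonest_casino(true_params),
    "extended-casino" = build_extended_casino(true_params),
    "cpg" = ,
    "cpg-island" = build_cpg_model(true_params),
    "toy1" = build_toy1(),
    "toy2" = build_toy2(),
    stop(sprintf("unknown example model '%s'", name))
  )
}
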