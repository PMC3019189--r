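# Brute-force oracles and random-model generators, written in plain R
# against the probability matrices only — deliberately independent of the
# package's dynamic-programming kernels.

# joint probability P(X, path) of a complete Start -> path -> End path
ref_path_prob <- function(model, state_idx, sym_idx) {
  S <- length(model$states)
  p <- model$trans[1L, state_idx[1L]] * model$emit[state_idx[1L], sym_idx[1L]]
  L <- length(sym_idx)
  if (L > 1L) {
    for (k in 2:L) {
      p <- p * model$trans[state_idx[k - 1L], state_idx[k]] *
        model$emit[state_idx[k], sym_idx[k]]
    }
  }
  p * model$trans[state_idx[L], S]
}

# all emitting-state paths of length L with their joint probabilities
ref_enumerate <- function(model, symbols) {
  sym_idx <- match(strsplit(symbols, "", fixed = TRUE)[[1L]], model$alphabet)
  em <- setdiff(seq_along(model$states), c(1L, length(model$states)))
  grid <- as.matrix(expand.grid(rep(list(em), length(sym_idx))))
  probs <- apply(grid, 1L, function(st) ref_path_prob(model, st, sym_idx))
  list(paths = grid, probs = probs, sym_idx = sym_idx)
}

ref_forward_prob <- function(model, symbols) sum(ref_enumerate(model, symbols)$probs)

ref_best_log_prob <- function(model, symbols) log(max(ref_enumerate(model, symbols)$probs))

# posterior over paths, dropping zero-probability paths
ref_posterior <- function(model, symbols) {
  en <- ref_enumerate(model, symbols)
  keep <- en$probs > 0
  list(paths = en$paths[keep, , drop = FALSE],
       probs = en$probs[keep] / sum(en$probs[keep]),
       sym_idx = en$sym_idx)
}

# transition/emission counts of an enumerated path as a flat named vector
ref_counts_key <- function(model, state_idx, sym_idx) {
  S <- length(model$states)
  A <- length(model$alphabet)
  tr <- matrix(0, S, S)
  em <- matrix(0, S, A)
  prev <- 1L
  for (k in seq_along(sym_idx)) {
    tr[prev, state_idx[k]] <- tr[prev, state_idx[k]] + 1
    em[state_idx[k], sym_idx[k]] <- em[state_idx[k], sym_idx[k]] + 1
    prev <- state_idx[k]
  }
  tr[prev, S] <- tr[prev, S] + 1
  paste(c(tr, em), collapse = ",")
}

counts_key <- function(cnt) paste(c(cnt$trans, cnt$emit), collapse = ",")

rdirichlet1 <- function(n) {
  g <- rexp(n)
  g / sum(g)
}

# random small HMM: random emitting-state count, alphabet size, transition
# support and Dirichlet-distributed probability rows
random_hmm <- function(max_emit = 4L, max_sym = 4L) {
  n_em <- sample(seq_len(max_emit), 1L)
  n_sym <- sample(2:max_sym, 1L)
  states <- c("Start", paste0("s", seq_len(n_em)), "End")
  alphabet <- letters[seq_len(n_sym)]
  S <- n_em + 2L
  trans <- matrix(0, S, S, dimnames = list(states, states))
  emit <- matrix(0, S, n_sym, dimnames = list(states, alphabet))
  start_targets <- which(stats::runif(n_em) < 0.7)
  if (length(start_targets) == 0L) start_targets <- sample(n_em, 1L)
  trans[1L, 1L + start_targets] <- rdirichlet1(length(start_targets))
  for (i in seq_len(n_em)) {
    succ <- which(stats::runif(n_em) < 0.7)
    # every emitting state keeps an End transition so ancestral draws stay
    # short and the End state is always reachable
    trans[1L + i, c(1L + succ, S)] <- rdirichlet1(length(succ) + 1L)
    emit[1L + i, ] <- rdirichlet1(n_sym)
  }
  hmm_model(states, alphabet, trans, emit)
}

# draw one sequence from the model by plain-R ancestral simulation,
# retrying until its length falls within [min_len, max_len]
ref_simulate <- function(model, min_len = 1L, max_len = 50L, tries = 200L) {
  S <- length(model$states)
  for (t in seq_len(tries)) {
    cur <- 1L
    sym <- character()
    repeat {
      cur <- sample.int(S, 1L, prob = model$trans[cur, ])
      if (cur == S) break
      if (length(sym) >= max_len + 1L) break
      sym <- c(sym, sample(model$alphabet, 1L, prob = model$emit[cur, ]))
    }
    if (cur == S && length(sym) >= min_len && length(sym) <= max_len) {
      return(paste(sym, collapse = ""))
    }
  }
  stop("could not draw a sequence in the requested length range")
}

random_case <- function(max_emit = 4L, max_sym = 4L, min_len = 1L, max_len = 50L) {
  repeat {
    model <- random_hmm(max_emit, max_sym)
    seqs <- tryCatch(ref_simulate(model, min_len, max_len), error = function(e) NULL)
    if (!is.null(seqs)) return(list(model = model, symbols = seqs))
  }
}

# reference two-step Viterbi training loop: full decode + explicit path
# counting, then the shared tying-aware update
ref_viterbi_train <- function(example, dataset, init, iterations, pseudocount = 1) {
  pz <- example$parameterization
  values <- init
  traj <- list()
  for (q in seq_len(iterations)) {
    m <- apply_parameters(example$model, pz, values)
    total <- NULL
    for (i in seq_len(nrow(dataset))) {
      p <- viterbi_decode(m, dataset$sequence[[i]])
      cnt <- path_counts(m, p$states, dataset$sequence[[i]])
      total <- if (is.null(total)) cnt else
        list(trans = total$trans + cnt$trans, emit = total$emit + cnt$emit)
    }
    agg <- aggregate_counts(total, pz)
    values <- update_parameters(agg, pz, pseudocount = pseudocount)
    traj[[q]] <- values
  }
  traj
}

# reference two-step EM loop over forward-backward expected counts
ref_bw_train <- function(example, dataset, init, iterations, pseudocount = 1) {
  pz <- example$parameterization
  values <- init
  traj <- list()
  for (q in seq_len(iterations)) {
    m <- apply_parameters(example$model, pz, values)
    total <- NULL
    for (i in seq_len(nrow(dataset))) {
      cnt <- expected_counts(m, dataset$sequence[[i]], engine = "forward-backward")
      total <- if (is.null(total)) cnt else
        list(trans = total$trans + cnt$trans, emit = total$emit + cnt$emit)
    }
    values <- update_parameters(aggregate_counts(total, pz), pz, pseudocount = pseudocount)
    traj[[q]] <- values
  }
  traj
}

# one iteration of two-step stochastic EM: forward matrix + back-traced
# sampled paths + explicit counting + shared update
ref_sem_iteration <- function(example, dataset, values, k, pseudocount = 1) {
  pz <- example$parameterization
  m <- apply_parameters(example$model, pz, values)
  total <- NULL
  for (i in seq_len(nrow(dataset))) {
    fw <- forward_probability(m, dataset$sequence[[i]])
    paths <- sample_posterior_paths(m, fw, n = k)
    for (p in paths) {
      cnt <- path_counts(m, p, dataset$sequence[[i]])
      total <- if (is.null(total)) cnt else
        list(trans = total$trans + cnt$trans, emit = total$emit + cnt$emit)
    }
  }
  update_parameters(aggregate_counts(total, pz), pz, pseudocount = pseudocount)
}
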