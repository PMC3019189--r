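#' Train HMM parameters
#'
#' Iterative count-based parameter training. Each iteration collects
#' transition/emission counts from every training sequence with the chosen
#' algorithm's one-pass linear-memory kernel, pools them over sequences
#' (and sampled chains), aggregates them onto the free parameters of the
#' tying scheme, and re-normalizes with pseudocounts:
#'
#' * `"viterbi"` — counts along each sequence's Viterbi path; the score is
#'   the summed log joint probability of sequence and path. Stops when the
#'   pooled count vector (optionally the exact traceback paths, via a
#'   rolling path hash) repeats between iterations.
#' * `"stochastic_em"` — counts along `k_paths` state paths per sequence
#'   sampled from the posterior; the score is the summed log-likelihood.
#'   Stops when the log-likelihood change falls below `tol`.
#' * `"baum_welch"` — posterior-expected counts (EM); same stopping rule.
#'
#' @param model Template [hmm_model()] (structure, alphabet, label codes).
#' @param parameterization An [hmm_parameterization()] for the model.
#' @param dataset Tibble with a `sequence` column (see
#'   [generate_dataset()], [read_sequences()]).
#' @param method Training algorithm.
#' @param init Named vector of initial parameter values; `NULL` draws
#'   random values via [random_initialize()] from a seed derived from
#'   `seed`.
#' @param k_paths Number of sampled paths per sequence and iteration
#'   (stochastic EM only).
#' @param max_iter Maximum number of iterations (>= 1).
#' @param pseudocount Added to each pooled parameter count before
#'   normalization; keeps rarely used parameters alive and prevents
#'   premature termination.
#' @param tol Absolute log-likelihood change below which stochastic EM and
#'   Baum-Welch stop; use 0 to always run `max_iter` iterations.
#' @param seed Root seed; per-iteration child seeds drive the samplers so
#'   runs replay exactly.
#' @param engine Expected-count engine for Baum-Welch (see
#'   [expected_counts()]).
#' @param convergence For Viterbi training: `"counts"` stops when the
#'   pooled count vector repeats; `"path_hash"` additionally requires the
#'   per-sequence traceback path hashes to repeat (strict path identity).
#'
#' @return An object of class `hmm_training_run`. Row `iteration = 0` of
#'   its trajectory holds the initial values; row `q` holds the values
#'   after the q-th update together with the score of the model that
#'   entered iteration q. See [tidy.hmm_training_run()],
#'   [glance.hmm_training_run()], [autoplot.hmm_training_run()].
#' @export
train_hmm <- function(model, parameterization, dataset,
                      method = c("viterbi", "stochastic_em", "baum_welch"),
                      init = NULL, k_paths = 1L, max_iter = 50L,
                      pseudocount = 1, tol = 1e-6, seed = NULL,
                      engine = c("linear", "forward-backward"),
                      convergence = c("counts", "path_hash")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  convergence <- match.arg(convergence)
  pz <- parameterization
  if (!is.data.frame(dataset) || nrow(dataset) == 0L) {
    stop("dataset must be a non-empty data frame with a 'sequence' column")
  }
  stopifnot(max_iter >= 1L, k_paths >= 1L, pseudocount >= 0)

  obs <- lapply(seq_len(nrow(dataset)), function(i) {
    encode_symbols(model, dataset$sequence[[i]], id = dataset$id[[i]] %||% i)
  })
  if (is.null(init)) {
    init <- random_initialize(pz, seed = if (is.null(seed)) NULL else child_seed(seed, "init"))
  }
  values <- init
  n_param <- nrow(pz$params)
  traj <- matrix(NA_real_, max_iter + 1L, n_param,
                 dimnames = list(NULL, pz$params$param))
  traj[1L, ] <- values[pz$params$param]
  loglik <- rep(NA_real_, max_iter + 1L)
  stop_reason <- "max_iterations"
  prev_counts <- NULL
  prev_hash <- NULL
  q_done <- 0L

  for (q in seq_len(max_iter)) {
    m <- apply_parameters(model, pz, values)
    total <- zero_counts(m)
    score <- 0
    hashes <- NULL

    if (method == "viterbi") {
      hashes <- numeric(length(obs))
      for (i in seq_along(obs)) {
        r <- tryCatch(
          .cpp_viterbi_counts(m$trans, m$emit, obs[[i]]),
          error = function(e) stop(sprintf("record %s: %s",
                                           dataset$id[[i]] %||% i, conditionMessage(e)),
                                   call. = FALSE))
        total$trans <- total$trans + r$trans_counts
        total$emit <- total$emit + r$emit_counts
        score <- score + r$log_prob
        hashes[i] <- r$path_hash
      }
    } else if (method == "stochastic_em") {
      s <- if (is.null(seed)) NULL else child_seed(seed, "sem-iter", q)
      total <- with_seed(s, {
        for (i in seq_along(obs)) {
          r <- tryCatch(
            .cpp_sem_counts(m$trans, m$emit, obs[[i]], as.integer(k_paths)),
            error = function(e) stop(sprintf("record %s: %s",
                                             dataset$id[[i]] %||% i, conditionMessage(e)),
                                     call. = FALSE))
          for (cc in seq_len(k_paths)) {
            total$trans <- total$trans + r$trans_counts[[cc]]
            total$emit <- total$emit + r$emit_counts[[cc]]
          }
          score <- score + r$log_prob
        }
        total
      })
    } else {
      fun <- if (engine == "linear") .cpp_expected_counts_linear else .cpp_expected_counts_fb
      for (i in seq_along(obs)) {
        r <- tryCatch(
          fun(m$trans, m$emit, obs[[i]]),
          error = function(e) stop(sprintf("record %s: %s",
                                           dataset$id[[i]] %||% i, conditionMessage(e)),
                                   call. = FALSE))
        total$trans <- total$trans + r$trans_counts
        total$emit <- total$emit + r$emit_counts
        score <- score + r$log_prob
      }
    }

    pooled <- param_counts_vector(total, pz)
    values <- update_parameters(pooled, pz, pseudocount = pseudocount)
    loglik[q + 1L] <- score
    traj[q + 1L, ] <- values[pz$params$param]
    q_done <- q

    if (method == "viterbi") {
      same <- !is.null(prev_counts) && isTRUE(all.equal(prev_counts, pooled, tolerance = 0))
      if (same && convergence == "path_hash") {
        same <- identical(prev_hash, hashes)
      }
      if (same) { stop_reason <- "paths_converged"; break }
      prev_counts <- pooled
      prev_hash <- hashes
    } else if (q > 1L && is.finite(tol) && tol > 0 &&
               abs(loglik[q + 1L] - loglik[q]) < tol) {
      stop_reason <- "loglik_converged"
      break
    }
  }

  structure(
    list(method = method, k_paths = if (method == "stochastic_em") k_paths else NA_integer_,
         engine = if (method == "baum_welch") engine else NA_character_,
         parameterization = pz,
         trajectory = traj[seq_len(q_done + 1L), , drop = FALSE],
         loglik = loglik[seq_len(q_done + 1L)],
         n_iterations = q_done,
         stop_reason = stop_reason,
         pseudocount = pseudocount, tol = tol, seed = seed,
         init = init),
    class = "hmm_training_run"
  )
}

#' @export
print.hmm_training_run <- function(x, ...) {
  cat(sprintf("<hmm_training_run> %s%s: %d iterations (%s), final score %.6g\n",
              x$method,
              if (!is.na(x$k_paths)) sprintf(" (K = %d)", x$k_paths) else "",
              x$n_iterations, x$stop_reason,
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Final parameter values of a training run
#' @param run An `hmm_training_run`.
#' @return Named numeric vector.
#' @export
final_values <- function(run) {
  v <- run$trajectory[nrow(run$trajectory), ]
  setNames(as.numeric(v), colnames(run$trajectory))
}

#' Viterbi training
#'
#' Convenience wrapper around [train_hmm()] with `method = "viterbi"`.
#' @inheritParams train_hmm
#' @param ... Passed to [train_hmm()].
#' @export
viterbi_train <- function(model, parameterization, dataset, ...) {
  train_hmm(model, parameterization, dataset, method = "viterbi", ...)
}

#' Stochastic EM training
#'
#' Convenience wrapper around [train_hmm()] with `method = "stochastic_em"`.
#' @inheritParams train_hmm
#' @param ... Passed to [train_hmm()].
#' @export
stochastic_em_train <- function(model, parameterization, dataset, k_paths = 1L, ...) {
  train_hmm(model, parameterization, dataset, method = "stochastic_em",
            k_paths = k_paths, ...)
}

#' Baum-Welch training
#'
#' Convenience wrapper around [train_hmm()] with `method = "baum_welch"`.
#' @inheritParams train_hmm
#' @param ... Passed to [train_hmm()].
#' @export
baum_welch_train <- function(model, parameterization, dataset, ...) {
  train_hmm(model, parameterization, dataset, method = "baum_welch", ...)
}
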