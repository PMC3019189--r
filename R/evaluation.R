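#' Per-position prediction accuracy of a trained model
#'
#' Viterbi-decodes every test sequence and scores the per-position binary
#' classification "position label is in the positive set" against the true
#' labels. Performance is the product of sensitivity and specificity.
#'
#' Two specificity conventions are supported: `"tnr"`, the true-negative
#' rate TN / (TN + FP) (default), and `"precision"`, TP / (TP + FP) (the
#' convention common in gene-prediction evaluation). Both quantities are
#' always returned; `specificity` and `performance` follow the chosen
#' mode.
#'
#' @param model A trained [hmm_model()].
#' @param dataset Tibble with `sequence` and `labels` columns.
#' @param positive_labels Character vector of label codes counted as
#'   positive (e.g. `"L"` for the loaded dice, `"+"` for CpG islands).
#' @param specificity_mode `"tnr"` or `"precision"`.
#' @return One-row tibble: confusion counts `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `tnr`, `precision`, `specificity`, `performance`,
#'   `specificity_mode`.
#' @export
decode_and_score <- function(model, dataset, positive_labels,
                             specificity_mode = c("tnr", "precision")) {
  specificity_mode <- match.arg(specificity_mode)
  if (!is.data.frame(dataset) || !"labels" %in% names(dataset) ||
      anyNA(dataset[["labels"]])) {
    stop("dataset must carry true labels for every record")
  }
  tp <- fn <- fp <- tn <- 0
  for (i in seq_len(nrow(dataset))) {
    truth <- strsplit(dataset$labels[[i]], "", fixed = TRUE)[[1L]]
    pred <- strsplit(viterbi_decode(model, dataset$sequence[[i]])$labels, "",
                     fixed = TRUE)[[1L]]
    if (length(truth) != length(pred)) {
      stop(sprintf("record %s: %d labels for %d predicted positions",
                   dataset$id[[i]] %||% i, length(truth), length(pred)))
    }
    tpos <- truth %in% positive_labels
    ppos <- pred %in% positive_labels
    tp <- tp + sum(tpos & ppos)
    fn <- fn + sum(tpos & !ppos)
    fp <- fp + sum(!tpos & ppos)
    tn <- tn + sum(!tpos & !ppos)
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  spec <- if (specificity_mode == "tnr") tnr else prec
  tibble(tp = tp, fn = fn, fp = fp, tn = tn,
         sensitivity = sens, tnr = tnr, precision = prec,
         specificity = spec, performance = sens * spec,
         specificity_mode = specificity_mode)
}

#' Distance between trained and true parameter values
#'
#' The parameter-convergence metric: the mean absolute difference between
#' trained and true values, computed separately over the free emission
#' parameters and the free transition parameters. Models with no free
#' emission parameters report `NA` for the emission distance.
#'
#' For models whose likelihood is invariant under a relabeling of states
#' (e.g. exchanging the fair and loaded dice), raw distances depend on
#' which of the equivalent optima training happened to reach. With
#' `align = "symmetry"` the distance is minimized over the supplied label
#' symmetries (each a named character vector mapping a trained parameter
#' to the true parameter it plays the role of); the identity is always a
#' candidate.
#'
#' @param trained Named numeric vector of trained values (see
#'   [final_values()]).
#' @param true_values Named numeric vector of the generating values.
#' @param parameterization The shared [hmm_parameterization()].
#' @param align `"none"` or `"symmetry"`.
#' @param symmetries List of named character vectors (see
#'   `build_dishonest_casino()$symmetries`).
#' @return One-row tibble: `emission_distance`, `transition_distance`.
#' @export
parameter_distance <- function(trained, true_values, parameterization,
                               align = c("none", "symmetry"), symmetries = NULL) {
  align <- match.arg(align)
  pz <- parameterization
  free <- pz$params[pz$params$role == "free", ]
  if (!all(free$param %in% names(trained))) {
    stop("trained values do not cover the free parameters: ",
         paste(setdiff(free$param, names(trained)), collapse = ", "))
  }
  perms <- list(identity = NULL)
  if (align == "symmetry" && length(symmetries) > 0L) {
    perms <- c(perms, symmetries)
  }
  best <- NULL
  best_total <- Inf
  for (perm in perms) {
    ref <- setNames(free$param, free$param)
    if (!is.null(perm)) ref[names(perm)[names(perm) %in% free$param]] <-
        perm[names(perm) %in% free$param]
    if (!all(ref %in% names(true_values))) {
      stop("true values do not cover the (permuted) free parameters")
    }
    d <- abs(trained[free$param] - true_values[ref])
    total <- mean(d)
    if (total < best_total) {
      best_total <- total
      em <- free$kind == "emit"
      best <- tibble(
        emission_distance = if (any(em)) mean(d[em]) else NA_real_,
        transition_distance = if (any(!em)) mean(d[!em]) else NA_real_
      )
    }
  }
  best
}

#' Cross-validated comparison of training algorithms
#'
#' Splits the dataset into `n_folds` near-equal folds; for each fold the
#' remaining sequences form the training set and the fold itself the test
#' set. Within a fold, all configurations share one random initialization
#' (so differences reflect the algorithms, not the starting point), are
#' trained for up to `max_iter` iterations, and after every iteration the
#' partially trained model is scored on the held-out fold and its
#' parameter distance to the generating values is recorded.
#'
#' @param example An `hmm_example` (see [build_dishonest_casino()]), or a
#'   list with `model`, `parameterization`, `true_values`,
#'   `positive_labels` and optional `symmetries`.
#' @param dataset Labeled dataset tibble (see [generate_dataset()]).
#' @param configs Tibble with columns `method` and `k` defining the
#'   training configurations; defaults to Viterbi, Baum-Welch and
#'   stochastic EM with 1, 3 and 5 sampled paths.
#' @param n_folds Number of cross-evaluation folds.
#' @param max_iter,pseudocount,tol Passed to [train_hmm()].
#' @param seed Root seed for fold assignment, initialization and training.
#' @param specificity_mode See [decode_and_score()].
#' @param align Parameter-distance alignment (see [parameter_distance()]).
#' @return An object of class `hmm_crossval`: `metrics` (tibble with one
#'   row per fold, configuration and iteration), `summary` (mean and sd
#'   over folds per configuration and iteration) and `folds`.
#' @export
cross_validate <- function(example, dataset,
                           configs = NULL, n_folds = 3L,
                           max_iter = 20L, pseudocount = 1, tol = 0,
                           seed = NULL, specificity_mode = c("tnr", "precision"),
                           align = c("none", "symmetry")) {
  specificity_mode <- match.arg(specificity_mode)
  align <- match.arg(align)
  if (is.null(configs)) {
    configs <- tibble(
      method = c("viterbi", "baum_welch", rep("stochastic_em", 3L)),
      k = c(NA, NA, 1L, 3L, 5L)
    )
  }
  n <- nrow(dataset)
  if (n < n_folds) stop("fewer sequences than folds")
  fold_of <- with_seed(if (is.null(seed)) NULL else child_seed(seed, "folds"),
                       sample(rep(seq_len(n_folds), length.out = n)))
  pz <- example$parameterization
  symmetries <- if (align == "symmetry") example$symmetries else NULL
  rows <- list()
  for (f in seq_len(n_folds)) {
    train_set <- dataset[fold_of != f, , drop = FALSE]
    test_set <- dataset[fold_of == f, , drop = FALSE]
    init <- random_initialize(
      pz, seed = if (is.null(seed)) NULL else child_seed(seed, "init", f))
    for (ci in seq_len(nrow(configs))) {
      method <- configs$method[[ci]]
      k <- configs$k[[ci]]
      run <- train_hmm(
        example$model, pz, train_set, method = method,
        init = init, k_paths = if (is.na(k)) 1L else k,
        max_iter = max_iter, pseudocount = pseudocount, tol = tol,
        seed = if (is.null(seed)) NULL else child_seed(seed, "train", f, ci))
      for (q in seq_len(run$n_iterations)) {
        vals <- setNames(as.numeric(run$trajectory[q + 1L, ]),
                         colnames(run$trajectory))
        m_q <- apply_parameters(example$model, pz, vals)
        sc <- decode_and_score(m_q, test_set, example$positive_labels,
                               specificity_mode = specificity_mode)
        pd <- parameter_distance(vals, example$true_values, pz,
                                 align = align, symmetries = symmetries)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(fold = f, method = method, k = k, iteration = q,
                 loglik = run$loglik[q + 1L]),
          sc[c("sensitivity", "specificity", "performance")], pd)
      }
    }
  }
  metrics <- dplyr::bind_rows(rows)
  summary <- metrics |>
    dplyr::group_by(.data$method, .data$k, .data$iteration) |>
    dplyr::summarise(dplyr::across(
      c("sensitivity", "specificity", "performance",
        "emission_distance", "transition_distance"),
      list(mean = ~mean(.x), sd = ~stats::sd(.x)), .names = "{.col}_{.fn}"),
      .groups = "drop")
  structure(list(metrics = metrics, summary = summary, folds = fold_of,
                 configs = configs),
            class = "hmm_crossval")
}

#' @export
print.hmm_crossval <- function(x, ...) {
  cat(sprintf("<hmm_crossval> %d folds x %d configurations, %d metric rows\n",
              max(x$folds), nrow(x$configs), nrow(x$metrics)))
  fin <- x$metrics |>
    dplyr::group_by(.data$fold, .data$method, .data$k) |>
    dplyr::slice_max(.data$iteration, n = 1L) |>
    dplyr::group_by(.data$method, .data$k) |>
    dplyr::summarise(performance = mean(.data$performance), .groups = "drop")
  print(fin)
  invisible(x)
}
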