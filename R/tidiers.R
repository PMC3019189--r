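# broom-style accessors and plots for training runs and cross-validation
# results

#' Tidy a training run
#'
#' @param x An `hmm_training_run` from [train_hmm()].
#' @param ... Unused.
#' @return Long tibble with one row per iteration and parameter:
#'   `iteration`, `param`, `role`, `kind`, `value`, `loglik`. Iteration 0
#'   holds the initial values (no score).
#' @method tidy hmm_training_run
#' @export
tidy.hmm_training_run <- function(x, ...) {
  traj <- as_tibble(x$trajectory)
  traj$iteration <- seq_len(nrow(traj)) - 1L
  traj$loglik <- x$loglik
  long <- tidyr::pivot_longer(traj, cols = -c("iteration", "loglik"),
                              names_to = "param", values_to = "value")
  info <- x$parameterization$params[c("param", "role", "kind")]
  dplyr::relocate(dplyr::left_join(long, info, by = "param"),
                  "iteration", "param", "role", "kind", "value", "loglik")
}

#' One-row summary of a training run
#'
#' @inheritParams tidy.hmm_training_run
#' @return Tibble: `method`, `k_paths`, `n_iterations`, `final_loglik`,
#'   `stop_reason`, `n_free_parameters`.
#' @method glance hmm_training_run
#' @export
glance.hmm_training_run <- function(x, ...) {
  tibble(method = x$method, k_paths = x$k_paths,
         n_iterations = x$n_iterations,
         final_loglik = x$loglik[length(x$loglik)],
         stop_reason = x$stop_reason,
         n_free_parameters = n_free_parameters(x$parameterization))
}

#' Plot a training run
#'
#' Score trajectory (top) and free-parameter trajectories (bottom).
#'
#' @param object An `hmm_training_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hmm_training_run
#' @export
autoplot.hmm_training_run <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$role == "free" & d$iteration > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$param)) +
    ggplot2::geom_line(show.legend = nrow(object$parameterization$params) <= 16) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "parameter value",
                  title = sprintf("%s training", object$method)) +
    ggplot2::theme_minimal()
}

#' @method tidy hmm_crossval
#' @export
tidy.hmm_crossval <- function(x, ...) x$metrics

#' @method glance hmm_crossval
#' @export
glance.hmm_crossval <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$fold, .data$method, .data$k) |>
    dplyr::slice_max(.data$iteration, n = 1L) |>
    dplyr::group_by(.data$method, .data$k) |>
    dplyr::summarise(
      performance = mean(.data$performance),
      transition_distance = mean(.data$transition_distance),
      emission_distance = mean(.data$emission_distance),
      .groups = "drop")
}

#' Plot cross-validation performance curves
#'
#' Mean held-out performance per iteration with a one-standard-deviation
#' ribbon over folds, one curve per training configuration.
#'
#' @param object An `hmm_crossval` from [cross_validate()].
#' @param metric Column of the summary to plot (default `"performance"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hmm_crossval
#' @export
autoplot.hmm_crossval <- function(object, metric = "performance", ...) {
  s <- object$summary
  s$config <- ifelse(is.na(s$k), s$method, sprintf("%s (K=%d)", s$method, s$k))
  mu <- s[[paste0(metric, "_mean")]]
  sd <- s[[paste0(metric, "_sd")]]
  s$mu <- mu
  s$lo <- mu - sd
  s$hi <- mu + sd
  ggplot2::ggplot(s, ggplot2::aes(x = .data$iteration, y = .data$mu,
                                  colour = .data$config, fill = .data$config)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = metric) +
    ggplot2::theme_minimal()
}
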