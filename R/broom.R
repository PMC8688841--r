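#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the loss history of a fit
#'
#' @param x An `msmda_fit`.
#' @param ... Unused.
#' @return Long tibble with columns `step`, `epoch`, `component`
#'   (`total`, `cls`, `mmd`, `disc`), `value`, plus `alpha` and `beta_eff`.
#' @method tidy msmda_fit
#' @export
tidy.msmda_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(
      cols = dplyr::starts_with("loss_"),
      names_to = "component", values_to = "value",
      names_prefix = "loss_"
    ) |>
    dplyr::select("step", "epoch", "component", "value", "alpha", "beta_eff")
}

#' One-row summary of a fit
#'
#' @param x An `msmda_fit`.
#' @param ... Unused.
#' @return One-row tibble: branch count, parameter count, epochs, steps,
#'   final loss components and final alpha.
#' @method glance msmda_fit
#' @export
glance.msmda_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble::tibble(
    n_branches = x$model_config$n_sources,
    n_parameters = n_parameters(x$params),
    epochs = x$train_config$epochs,
    steps = nrow(h),
    final_loss_total = last$loss_total,
    final_loss_cls = last$loss_cls,
    final_loss_mmd = last$loss_mmd,
    final_loss_disc = last$loss_disc,
    final_alpha = last$alpha
  )
}

#' Plot the training-loss trajectories of a fit
#'
#' Loss components and the alpha schedule against the training step,
#' faceted per curve.
#'
#' @param object An `msmda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msmda_fit
#' @export
autoplot.msmda_fit <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::select("step", "component", "value")
  alpha_df <- tibble::tibble(step = object$history$step,
                             component = "alpha",
                             value = object$history$alpha)
  dplyr::bind_rows(long, alpha_df) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "training step", y = NULL,
                  title = "MS-MDA training trajectories") +
    ggplot2::theme_minimal()
}

#' Plot accuracy against the number of source branches
#'
#' @param records Output of [run_source_sweep()].
#' @return A ggplot object: per-seed points and the mean curve.
#' @export
plot_source_sweep <- function(records) {
  means <- records |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(records, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = means, colour = "#d95f02", linewidth = 1) +
    ggplot2::scale_x_continuous(breaks = unique(records$k)) +
    ggplot2::labs(x = "number of source branches", y = "target accuracy",
                  title = "Accuracy vs number of sources") +
    ggplot2::theme_minimal()
}

#' Plot the normalization-study grid
#'
#' @param records Output of [run_normalization_grid()].
#' @return A ggplot object: mean accuracy per normalization type, faceted by
#'   method, coloured by application order.
#' @export
plot_normalization_grid <- function(records) {
  means <- records |>
    dplyr::group_by(.data$method, .data$normalization, .data$norm_order) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$normalization,
                                      y = .data$accuracy,
                                      fill = .data$norm_order)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "mean target accuracy",
                  title = "Normalization study") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom rlang .data
NULL
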