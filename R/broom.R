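#' Tidiers and plots for evaluation reports and fits
#'
#' `tidy()` on a `gofusion_eval` returns the per-threshold
#' precision/recall/F sweep; `glance()` returns the one-row scalar summary.
#' `tidy()` on a `gofusion_model` returns the per-epoch loss trace and
#' learning rate; `glance()` summarizes the fit. `autoplot()` draws the
#' precision-recall sweep (eval) or the loss trace (model).
#'
#' @param x A `gofusion_eval` or `gofusion_model`.
#' @param ... Unused.
#' @return A tibble (`tidy`/`glance`) or a ggplot (`autoplot`).
#' @name gofusion-tidiers
NULL

#' @rdname gofusion-tidiers
#' @method tidy gofusion_eval
#' @export
tidy.gofusion_eval <- function(x, ...) {
  x$curve
}

#' @rdname gofusion-tidiers
#' @method glance gofusion_eval
#' @export
glance.gofusion_eval <- function(x, ...) {
  tibble::tibble(fmax = x$fmax, tau = x$tau, f1 = x$f1, aupr = x$aupr,
                 mcc = x$mcc, n = x$n, gamma = x$gamma)
}

#' @rdname gofusion-tidiers
#' @method tidy gofusion_model
#' @export
tidy.gofusion_model <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$loss_trace),
    loss = x$loss_trace,
    lr = vapply(seq_along(x$loss_trace),
                function(e) lr_at_epoch(x$config, e), numeric(1))
  )
}

#' @rdname gofusion-tidiers
#' @method glance gofusion_model
#' @export
glance.gofusion_model <- function(x, ...) {
  tibble::tibble(
    aspect = x$aspect,
    gamma = x$label_space$gamma,
    modules = paste(sort(x$modules), collapse = "+"),
    epochs = length(x$loss_trace),
    initial_loss = x$loss_trace[1],
    final_loss = utils::tail(x$loss_trace, 1),
    n_train = x$n_train
  )
}

#' @rdname gofusion-tidiers
#' @method autoplot gofusion_eval
#' @export
autoplot.gofusion_eval <- function(x, ...) {
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$recall,
                                        y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(
      data = x$curve[x$curve$tau == x$tau, , drop = FALSE],
      color = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Fmax = %.3f at tau = %.2f", x$fmax, x$tau),
      x = "recall (protein-averaged)", y = "precision (protein-averaged)") +
    ggplot2::theme_minimal()
}

#' @rdname gofusion-tidiers
#' @method autoplot gofusion_model
#' @export
autoplot.gofusion_model <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training loss", x = "epoch", y = "mean BCE") +
    ggplot2::theme_minimal()
}

#' Ablation comparison plot
#'
#' @param sweep Output of [ablation_sweep()].
#' @param metric Metric column to plot.
#' @return A ggplot.
#' @export
plot_ablation <- function(sweep, metric = "aupr") {
  sweep$variant <- stats::reorder(sweep$variant, sweep[[metric]])
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$variant,
                                      y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
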