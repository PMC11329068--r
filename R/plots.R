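#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training history of a fitted fusion model
#'
#' Train (and validation, when present) loss against epoch.
#'
#' @param object A `fusion_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  h <- h[!is.na(h$loss), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of evaluation records
#'
#' Localization error and AUPRC per method (or per ablation model).
#'
#' @param object An `esi_records` tibble.
#' @param metric `"le_mm"` or `"auprc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esi_records <- function(object, metric = c("le_mm", "auprc"), ...) {
  metric <- match.arg(metric)
  key <- if ("model" %in% names(object)) "model" else "method"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[key]], y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "le_mm") "localization error (mm)" else "AUPRC") +
    ggplot2::theme_minimal()
}

#' Optimization history of a hyperparameter search
#'
#' Objective per trial with the running best overlaid.
#'
#' @param object A `tune_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tune_result <- function(object, ...) {
  h <- object$history
  h$best <- cummax(h$objective)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best), colour = "red") +
    ggplot2::labs(x = "trial", y = "mean validation AUPRC") +
    ggplot2::theme_minimal()
}

#' Plot an input matrix as a topographic map
#'
#' @param x An `input_matrix` (or bare matrix).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_topography <- function(x, ...) {
  m <- if (inherits(x, "input_matrix")) x$values else as.matrix(x)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
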