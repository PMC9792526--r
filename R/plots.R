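#' Plot per-class feature importance
#'
#' Horizontal stacked bars of mean |attribution| per feature, colored by
#' risk state, features ordered by overall importance.
#'
#' @param imp Importance tibble from [importance()].
#' @param top_n Show only the `top_n` most important features.
#' @return A ggplot object.
#' @export
plot_importance <- function(imp, top_n = 20) {
  df <- head(imp, top_n)
  classes <- setdiff(names(df), c("feature", "overall", "rank"))
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(classes),
                              names_to = "state", values_to = "value")
  long$feature <- factor(long$feature, levels = rev(df$feature))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$value, y = .data$feature,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot force-record contributions for one sample
#'
#' Signed contribution bars from the base value toward the model output.
#'
#' @param rec A `force_record` from [force_data()].
#' @param top_n Largest-magnitude contributions to show.
#' @return A ggplot object.
#' @export
plot_force <- function(rec, top_n = 12) {
  df <- head(tibble::as_tibble(rec), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$direction <- ifelse(df$contribution >= 0, "raises", "lowers")
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$contribution, y = .data$feature,
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      title = sprintf("%s state: base %.3f -> output %.3f",
                      attr(rec, "state"), attr(rec, "y_base"),
                      attr(rec, "model_output")),
      x = "contribution to logit", y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot dependence data
#'
#' Attribution of a feature against its value, colored by a second
#' feature — the spread at a given x reveals interaction with the
#' coloring feature.
#'
#' @param dep Tibble from [dependence_data()].
#' @param normal_range Optional length-2 band drawn as dotted guides.
#' @return A ggplot object.
#' @export
plot_dependence <- function(dep, normal_range = NULL) {
  p <- ggplot2::ggplot(dep,
                       ggplot2::aes(x = .data$value, y = .data$phi,
                                    color = .data$color_value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = dep$feature[1],
      y = sprintf("Shapley value (%s)", dep$class[1]),
      color = dep$color_feature[1]
    ) +
    ggplot2::theme_minimal()
  if (!is.null(normal_range)) {
    p <- p + ggplot2::geom_vline(xintercept = normal_range,
                                 linetype = 3, color = "darkgreen")
  }
  p
}

#' Training-history plot for a fitted model
#'
#' @param object A fitted `strokeqi_model`.
#' @param ... Unused.
#' @return A ggplot object with train and validation loss per epoch.
#' @export
autoplot.strokeqi_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, cols = c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
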