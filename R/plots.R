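#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_ribbon labs theme_minimal coord_flip
NULL

#' Plot training and validation loss curves
#'
#' @param object A fitted `nhits_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nhits_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "N-HiTS training history") +
    theme_minimal()
}

#' Plot a feature importance ranking
#'
#' @param object A `feature_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_ranking <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = factor(.data$feature,
                                       levels = rev(.data$feature)))
  ggplot(df, aes(x = .data$feature, y = .data$importance)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "normalized split-gain importance") +
    theme_minimal()
}

#' Plot a backward-elimination trace
#'
#' @param object A `backward_elimination`.
#' @param ... Unused.
#' @return A ggplot of validation RMSE against subset size.
#' @exportS3Method ggplot2::autoplot
autoplot.backward_elimination <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$n_features, y = .data$rmse)) +
    geom_line() + geom_point() +
    labs(x = "number of features", y = "validation RMSE") +
    theme_minimal()
}

#' Plot the Pareto front of an SMPSO run
#'
#' @param object An `smpso_result`.
#' @param ... Unused.
#' @return A ggplot of archive entries in (MAE, CWC) space.
#' @exportS3Method ggplot2::autoplot
autoplot.smpso_result <- function(object, ...) {
  df <- tidy.smpso_result(object)
  ggplot(df, aes(x = .data$mae, y = .data$cwc)) +
    geom_point() +
    labs(x = "validation MAE", y = "validation CWC",
         title = "Pareto archive") +
    theme_minimal()
}

#' Ribbon plot of an interval forecast against observations
#'
#' @param forecast A forecast tibble with columns `timestamp` (or `step`),
#'   `lower`, `median`, `upper` (as produced by [forecast_next()] or
#'   [tidy.interval_forecast()]).
#' @param observed Optional tibble with `timestamp` (or `step`) and
#'   `observed` columns to overlay.
#' @return A ggplot.
#' @export
plot_forecast <- function(forecast, observed = NULL) {
  xvar <- if ("timestamp" %in% names(forecast)) "timestamp" else "step"
  p <- ggplot(forecast, aes(x = .data[[xvar]])) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.3) +
    geom_line(aes(y = .data$median)) +
    labs(x = xvar, y = "target", title = "interval forecast") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_point(data = observed, aes(y = .data$observed))
  }
  p
}
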