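#' Point forecast metrics
#'
#' RMSE, MAE, and MAPE of a point forecast:
#' `RMSE = sqrt(mean((Y - y)^2))`, `MAE = mean(|Y - y|)`,
#' `MAPE = 100 * mean(|(Y - y)/y|)` (percent).
#'
#' @param predicted Numeric vector or matrix of predictions `Y`.
#' @param observed Observations `y`, same length.
#' @return A one-row tibble with columns `rmse`, `mae`, `mape`.
#' @export
point_metrics <- function(predicted, observed) {
  Y <- as.numeric(predicted)
  y <- as.numeric(observed)
  if (length(Y) != length(y) || length(y) == 0L) {
    stop("predicted and observed must have equal nonzero length", call. = FALSE)
  }
  if (any(abs(y) < 1e-8)) {
    stop("MAPE undefined: observed value(s) within 1e-8 of zero", call. = FALSE)
  }
  e <- Y - y
  tibble::tibble(rmse = sqrt(mean(e^2)),
                 mae = mean(abs(e)),
                 mape = 100 * mean(abs(e / y)))
}

#' Prediction interval metrics
#'
#' Coverage and width quality of prediction intervals:
#' \itemize{
#'   \item `PICP`: fraction of observations inside their (closed) interval;
#'   \item `PINAW = mean(U - L) / A`;
#'   \item `PINRW = sqrt(mean((U - L)^2)) / A`;
#'   \item `CWC = PINAW * (1 + gamma * exp(-eta * (PICP - mu)))` with
#'     `gamma = 0` when `PICP >= mu` and `1` otherwise.
#' }
#' `A` is the normalization range of the target (the `xmax - xmin` recorded
#' when the target channel was min-max scaled).
#'
#' @param observed Observations.
#' @param lower,upper Interval bounds, elementwise `lower <= upper`.
#' @param range_a Normalization range `A` (> 0).
#' @param mu_threshold Minimum acceptable PICP (default 0.80).
#' @param eta Penalty coefficient (default 1).
#' @return A one-row tibble with columns `picp`, `pinaw`, `pinrw`, `cwc`.
#' @export
interval_metrics <- function(observed, lower, upper, range_a,
                             mu_threshold = 0.80, eta = 1) {
  y <- as.numeric(observed)
  L <- as.numeric(lower)
  U <- as.numeric(upper)
  if (length(y) == 0L || length(L) != length(y) || length(U) != length(y)) {
    stop("observed, lower, upper must have equal nonzero length", call. = FALSE)
  }
  if (any(L > U + 1e-12)) stop("lower bound exceeds upper bound", call. = FALSE)
  if (!is.finite(range_a) || range_a <= 0) stop("normalization range A must be > 0", call. = FALSE)
  if (mu_threshold <= 0 || mu_threshold >= 1) stop("mu_threshold must be in (0, 1)", call. = FALSE)
  if (eta < 0) stop("eta must be >= 0", call. = FALSE)
  picp <- mean(y >= L & y <= U)
  w <- U - L
  pinaw <- mean(abs(w)) / range_a
  pinrw <- sqrt(mean(w^2)) / range_a
  gamma <- if (picp >= mu_threshold) 0 else 1
  cwc <- pinaw * (1 + gamma * exp(-eta * (picp - mu_threshold)))
  tibble::tibble(picp = picp, pinaw = pinaw, pinrw = pinrw, cwc = cwc)
}
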