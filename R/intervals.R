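#' Gaussian output heads
#'
#' Maps a hidden representation to the parameters of a Gaussian predictive
#' distribution: an affine mean head `mu = ht %*% w_mu + b_mu`, and a scale
#' head passed through the softplus `log(1 + exp(.))` plus a floor of 1e-6
#' so the standard deviation is strictly positive.
#'
#' @param ht Hidden representation: numeric vector or `batch x units` matrix.
#' @param w_mu,b_mu Mean head weights (units x out) and bias.
#' @param w_sigma,b_sigma Scale head weights and bias.
#' @param sigma_floor Additive floor on sigma (default 1e-6).
#' @return A list with `mu` and `sigma` of matching shape.
#' @export
gaussian_heads <- function(ht, w_mu, b_mu, w_sigma, b_sigma,
                           sigma_floor = 1e-6) {
  if (!is.matrix(ht)) ht <- matrix(ht, nrow = 1L)
  if (!all(is.finite(ht))) stop("non-finite hidden representation", call. = FALSE)
  mu <- sweep(ht %*% w_mu, 2L, b_mu, `+`)
  pre <- sweep(ht %*% w_sigma, 2L, b_sigma, `+`)
  list(mu = mu, sigma = softplus(pre) + sigma_floor)
}

#' Gaussian negative log-likelihood
#'
#' Mean over elements of `0.5 * log(2 * pi * sigma^2) + (c - mu)^2 /
#' (2 * sigma^2)`; minimizing it maximizes the Gaussian likelihood of the
#' observed futures.
#'
#' @param observed Observed future targets `c`.
#' @param mu,sigma Predictive mean and standard deviation (same shape;
#'   `sigma > 0`).
#' @return Scalar loss.
#' @export
gaussian_nll <- function(observed, mu, sigma) {
  if (length(observed) != length(mu) || length(mu) != length(sigma)) {
    stop("observed, mu, sigma must have equal length", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  mean(0.5 * log(2 * pi * sigma^2) + (observed - mu)^2 / (2 * sigma^2))
}

#' Monte-Carlo prediction intervals from Gaussian parameters
#'
#' Draws `n_samples` independent values from `N(mu, sigma)` for each
#' forecast step and takes empirical quantiles: the `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles bound the interval and the 50% quantile is
#' the median, which serves as the point forecast.
#'
#' @param mu,sigma Matrices (windows x horizon) or vectors of Gaussian
#'   parameters.
#' @param n_samples Draws per step (default 500).
#' @param level Confidence level in (0, 1) (default 0.90).
#' @param seed RNG seed.
#' @return A list of class `interval_forecast` with `lower`, `median`,
#'   `upper` (same shape as `mu`) and `level`.
#' @export
mc_intervals <- function(mu, sigma, n_samples = 500L, level = 0.90, seed = 1L) {
  stopifnot(n_samples >= 2, level > 0, level < 1)
  was_vec <- !is.matrix(mu)
  if (was_vec) { mu <- matrix(mu, nrow = 1L); sigma <- matrix(sigma, nrow = 1L) }
  stopifnot(all(dim(mu) == dim(sigma)))
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  lower <- med <- upper <- mu * 0
  local_seed(seed, {
    for (j in seq_len(ncol(mu))) {
      draws <- matrix(rnorm(nrow(mu) * n_samples), nrow(mu), n_samples)
      draws <- mu[, j] + sigma[, j] * draws
      qs <- apply(draws, 1L, stats::quantile, probs = probs, names = FALSE)
      lower[, j] <- qs[1L, ]; med[, j] <- qs[2L, ]; upper[, j] <- qs[3L, ]
    }
  })
  if (was_vec) { lower <- drop(lower); med <- drop(med); upper <- drop(upper) }
  structure(list(lower = lower, median = med, upper = upper, level = level),
            class = "interval_forecast")
}

#' Train the Gaussian-likelihood N-HiTS forecaster
#'
#' Convenience wrapper around [fit_nhits()] with the Gaussian loss: the
#' forecast path carries a mean channel and a pre-softplus scale channel,
#' each hierarchically interpolated and summed across blocks; the residual
#' backcast chain acts on the target history; training minimizes the
#' Gaussian negative log-likelihood. Downstream, the Monte-Carlo interval
#' median is the point forecast.
#'
#' @inheritParams fit_nhits
#' @param ... Overrides passed to [nhits_config()].
#' @return A fitted `nhits_model` with `loss = "gaussian"`.
#' @export
fit_nhits_g <- function(train_windows, val_windows, config = NULL, ...) {
  if (is.null(config)) {
    config <- nhits_config(lookback = train_windows$lookback,
                           horizon = train_windows$horizon,
                           loss = "gaussian", ...)
  }
  if (config$loss != "gaussian") stop("config loss must be 'gaussian'", call. = FALSE)
  fit_nhits(train_windows, val_windows, config)
}

#' Interval constructors from validation residuals
#'
#' Builds the two classical interval baselines from per-step validation
#' residuals (`observed - point forecast`):
#' \itemize{
#'   \item `error_fit`: Gaussian-kernel density (Silverman bandwidth) fitted
#'     to each step's residual pool; interval offsets are quantiles of the
#'     fitted density.
#'   \item `bootstrap`: interval offsets are empirical quantiles of 2,000
#'     seeded resamples (with replacement) of each step's residual pool.
#' }
#' The returned calibrator shifts any point-forecast matrix by the per-step
#' offsets.
#'
#' @param residuals Matrix (validation windows x horizon) of residuals, or a
#'   vector for a single-step task.
#' @param method `"error_fit"` or `"bootstrap"`.
#' @param level Confidence level (default 0.90).
#' @param n_boot Bootstrap resample count (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `interval_calibrator` with per-step `lower`
#'   and `upper` offsets; apply it with [apply_calibrator()].
#' @export
interval_from_errors <- function(residuals, method = c("error_fit", "bootstrap"),
                                 level = 0.90, n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (!is.matrix(residuals)) residuals <- matrix(residuals, ncol = 1L)
  if (nrow(residuals) < 10L) {
    stop("need at least 10 validation residuals per step", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  H <- ncol(residuals)
  lo <- up <- numeric(H)
  for (h in seq_len(H)) {
    r <- residuals[, h]
    if (method == "error_fit") {
      q <- kde_quantiles(r, probs)
    } else {
      q <- local_seed(seed + h, {
        stats::quantile(sample(r, n_boot, replace = TRUE), probs, names = FALSE)
      })
    }
    lo[h] <- q[1L]; up[h] <- q[2L]
  }
  structure(list(lower = lo, upper = up, level = level, method = method),
            class = "interval_calibrator")
}

# Quantiles of a Gaussian-kernel density estimate (Silverman's rule), by
# inverting the exact mixture CDF on a fine grid.
kde_quantiles <- function(x, probs) {
  if (stats::sd(x) == 0) return(rep(x[1L], length(probs)))
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x) - 4 * bw, max(x) + 4 * bw, length.out = 2048L)
  cdf <- vapply(grid, function(g) mean(stats::pnorm((g - x) / bw)), 0)
  stats::approx(cdf, grid, xout = probs, ties = "ordered", rule = 2)$y
}

#' Apply an interval calibrator to point forecasts
#'
#' @param calibrator An `interval_calibrator` from [interval_from_errors()].
#' @param point Matrix (windows x horizon) or vector of point forecasts.
#' @return An `interval_forecast` list with `lower`, `median`, `upper`.
#' @export
apply_calibrator <- function(calibrator, point) {
  was_vec <- !is.matrix(point)
  if (was_vec) point <- matrix(point, ncol = length(calibrator$lower))
  lower <- sweep(point, 2L, calibrator$lower, `+`)
  upper <- sweep(point, 2L, calibrator$upper, `+`)
  if (was_vec) { lower <- drop(lower); upper <- drop(upper); point <- drop(point) }
  structure(list(lower = lower, median = point, upper = upper,
                 level = calibrator$level),
            class = "interval_forecast")
}

#' Pinball (quantile) loss
#'
#' `mean(q * max(c - pred, 0) + (1 - q) * max(pred - c, 0))`: the
#' asymmetric loss whose minimizer is the `q`-th conditional quantile.
#' Training three heads at `(1 - level)/2`, `0.5`, and `1 - (1 - level)/2`
#' yields the quantile-loss interval baseline.
#'
#' @param observed Observed values `c`.
#' @param predicted Predicted `q`-th quantile.
#' @param q Quantile level in (0, 1).
#' @return Scalar loss.
#' @export
pinball_loss <- function(observed, predicted, q) {
  stopifnot(q > 0, q < 1, length(observed) == length(predicted))
  e <- observed - predicted
  mean(q * pmax(e, 0) + (1 - q) * pmax(-e, 0))
}
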