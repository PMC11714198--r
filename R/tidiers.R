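#' @importFrom generics tidy glance
NULL

#' Tidy a fitted N-HiTS model's training history
#'
#' @param x A fitted `nhits_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`.
#' @exportS3Method generics::tidy
tidy.nhits_model <- function(x, ...) x$history

#' One-row summary of a fitted N-HiTS model
#'
#' @param x A fitted `nhits_model`.
#' @param ... Unused.
#' @return A one-row tibble: loss name, architecture counts, epochs run,
#'   best epoch and best validation loss.
#' @exportS3Method generics::glance
glance.nhits_model <- function(x, ...) {
  tibble::tibble(loss = x$config$loss,
                 n_stacks = x$config$n_stacks,
                 n_blocks = length(x$blocks),
                 mlp_units = x$config$mlp_units,
                 lookback = x$config$lookback,
                 horizon = x$config$horizon,
                 epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss)
}

#' Tidy a feature ranking
#'
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @return The ranking tibble (`feature`, `importance`).
#' @exportS3Method generics::tidy
tidy.feature_ranking <- function(x, ...) tibble::as_tibble(x)

#' Tidy a backward-elimination trace
#'
#' @param x A `backward_elimination`.
#' @param ... Unused.
#' @return A tibble with one row per subset size: `n_features`, `features`
#'   (list-column), `rmse`, and whether the row is the chosen subset.
#' @exportS3Method generics::tidy
tidy.backward_elimination <- function(x, ...) {
  dplyr::mutate(x$trace,
                selected = vapply(.data$features, identical, TRUE,
                                  y = x$best_features))
}

#' Tidy a Pareto archive
#'
#' @param x An `smpso_result`.
#' @param ... Unused.
#' @return A tibble with the decoded archive entries and their objectives.
#' @exportS3Method generics::tidy
tidy.smpso_result <- function(x, ...) {
  n <- archive_size(x$archive)
  if (n == 0L) return(tibble::tibble())
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    hp <- decode_position(x$archive$positions[i, ], x$space)
    tibble::as_tibble_row(c(as.list(hp),
                            list(mae = x$archive$objectives[i, 1L],
                                 cwc = x$archive$objectives[i, 2L])))
  }))
}

#' One-row summary of an SMPSO run
#'
#' @param x An `smpso_result`.
#' @param ... Unused.
#' @return A one-row tibble with evaluation counts and archive size.
#' @exportS3Method generics::glance
glance.smpso_result <- function(x, ...) {
  tibble::tibble(n_evaluations = x$n_evaluations,
                 n_failures = x$n_failures,
                 archive_size = archive_size(x$archive),
                 seed = x$seed)
}

#' Tidy an interval forecast into long form
#'
#' @param x An `interval_forecast` (matrices windows x horizon).
#' @param ... Unused.
#' @return A tibble with columns `window`, `step`, `lower`, `median`,
#'   `upper`, `level`.
#' @exportS3Method generics::tidy
tidy.interval_forecast <- function(x, ...) {
  lower <- if (is.matrix(x$lower)) x$lower else matrix(x$lower, nrow = 1L)
  med <- if (is.matrix(x$median)) x$median else matrix(x$median, nrow = 1L)
  upper <- if (is.matrix(x$upper)) x$upper else matrix(x$upper, nrow = 1L)
  tibble::tibble(window = rep(seq_len(nrow(lower)), ncol(lower)),
                 step = rep(seq_len(ncol(lower)), each = nrow(lower)),
                 lower = as.vector(lower), median = as.vector(med),
                 upper = as.vector(upper), level = x$level)
}
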