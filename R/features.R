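#' Turn a series into lagged supervised learning data
#'
#' Row `t` of the result pairs the values of every channel at `t - lag`
#' (the "previous time period" features) with the target channel at `t`;
#' the first `lag` rows are dropped.
#'
#' @param series A gap-free series tibble.
#' @param target Name of the target channel.
#' @param lag Lag in steps (default 1).
#' @return A list with `features` (tibble, columns `<channel>_lag<lag>`) and
#'   `target` (numeric vector), both of length `nrow(series) - lag`.
#' @export
lag_supervise <- function(series, target, lag = 1L) {
  stopifnot(lag >= 1)
  n <- nrow(series)
  if (n < lag + 1L) stop("series shorter than lag + 1", call. = FALSE)
  chs <- series_channels(series)
  if (!target %in% chs) stop("unknown target channel '", target, "'", call. = FALSE)
  keep <- (lag + 1L):n
  feats <- lapply(chs, function(ch) series[[ch]][keep - lag])
  names(feats) <- paste0(chs, "_lag", lag)
  list(features = tibble::as_tibble(feats), target = series[[target]][keep])
}

# Fit a gradient-boosted-tree regressor (xgboost) with near-default
# settings; single thread for determinism.
fit_gbt <- function(features, target, nrounds = 60, seed = 1L, params = list()) {
  x <- as.matrix(features)
  p <- utils::modifyList(
    list(objective = "reg:squarederror", max_depth = 6, eta = 0.3,
         nthread = 1, verbosity = 0, seed = as.integer(seed)),
    params)
  dm <- xgboost::xgb.DMatrix(x, label = target, nthread = 1)
  xgboost::xgb.train(params = p, data = dm, nrounds = nrounds)
}

# Total split gain per feature, from the fitted booster's tree dump.
gbt_gain <- function(fit) {
  trees <- xgboost::xgb.model.dt.tree(model = fit)
  splits <- trees[!is.na(trees$Gain) & trees$Feature != "Leaf", ]
  if (nrow(splits) == 0L) return(numeric(0))
  tapply(splits$Gain, splits$Feature, sum)
}

#' Rank features by gradient-boosted-tree split-gain importance
#'
#' Fits a boosted-tree regressor and returns per-feature split-gain
#' importance, normalized to sum to 1 and sorted in decreasing order.
#' Features the trees never split on get importance 0.
#'
#' @param features A data frame of numeric predictors.
#' @param target Numeric response vector.
#' @param nrounds Boosting rounds (default 60).
#' @param seed Seed for the estimator.
#' @param params Optional list of booster parameter overrides.
#' @return A tibble of class `feature_ranking` with columns `feature`,
#'   `importance`.
#' @export
rank_importance <- function(features, target, nrounds = 60, seed = 1L,
                            params = list()) {
  stopifnot(nrow(features) == length(target))
  fit <- fit_gbt(features, target, nrounds = nrounds, seed = seed, params = params)
  imp <- gbt_gain(fit)
  gain <- stats::setNames(rep(0, ncol(features)), colnames(features))
  gain[names(imp)] <- imp
  total <- sum(gain)
  if (total > 0) gain <- gain / total
  ord <- order(gain, decreasing = TRUE)
  structure(tibble::tibble(feature = names(gain)[ord],
                           importance = unname(gain[ord])),
            class = c("feature_ranking", class(tibble::tibble())))
}

#' Backward elimination over a fixed importance ranking
#'
#' Starting from the full feature set, repeatedly drops the lowest-ranked
#' remaining feature, refits the boosted-tree regressor on the chronological
#' training block, and records validation RMSE. The chosen subset minimizes
#' validation RMSE; ties go to the smaller subset.
#'
#' @param features Data frame of predictors (rows chronological).
#' @param target Numeric response.
#' @param ranking A `feature_ranking` covering all columns of `features`;
#'   computed internally when `NULL`.
#' @param val_fraction Fraction of rows (the final block) held out for
#'   validation (default 0.3).
#' @param nrounds,seed,params Passed to the boosted-tree fits.
#' @return An object of class `backward_elimination`: list with `trace`
#'   (tibble: `n_features`, `features` list-column, `rmse`), `best_features`
#'   (character), and `ranking`.
#' @export
backward_eliminate <- function(features, target, ranking = NULL,
                               val_fraction = 0.3, nrounds = 60, seed = 1L,
                               params = list()) {
  stopifnot(nrow(features) == length(target))
  if (is.null(ranking)) {
    ranking <- rank_importance(features, target, nrounds = nrounds,
                               seed = seed, params = params)
  }
  if (!setequal(ranking$feature, colnames(features))) {
    stop("ranking must cover exactly the feature columns", call. = FALSE)
  }
  n <- nrow(features)
  n_val <- max(1L, floor(val_fraction * n))
  train_idx <- seq_len(n - n_val)
  val_idx <- (n - n_val + 1L):n
  sizes <- seq(ncol(features), 1L)
  rmses <- numeric(length(sizes))
  sets <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    sub <- ranking$feature[seq_len(sizes[i])]
    fit <- fit_gbt(features[train_idx, sub, drop = FALSE], target[train_idx],
                   nrounds = nrounds, seed = seed, params = params)
    pred <- stats::predict(fit, as.matrix(features[val_idx, sub, drop = FALSE]))
    rmses[i] <- sqrt(mean((pred - target[val_idx])^2))
    sets[[i]] <- sub
  }
  # minimum RMSE; among ties (within double precision) prefer fewer features
  best <- which(rmses <= min(rmses) + 1e-12)
  best <- best[which.min(sizes[best])]
  structure(list(
    trace = tibble::tibble(n_features = sizes, features = sets, rmse = rmses),
    best_features = sets[[best]],
    ranking = ranking),
    class = "backward_elimination")
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat(sprintf("backward elimination over %d features; best subset (%d): %s\n",
              max(x$trace$n_features), length(x$best_features),
              paste(x$best_features, collapse = ", ")))
  invisible(x)
}

#' Map selected lagged feature names back to series channels
#'
#' @param features Character vector of lagged feature names
#'   (`<channel>_lag<k>`).
#' @return Character vector of channel names.
#' @export
lagged_to_channels <- function(features) {
  unique(sub("_lag[0-9]+$", "", features))
}
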