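#' Read a multivariate sensor series from CSV
#'
#' Reads a sensor log with a header row naming one timestamp column and one
#' or more numeric channels, sorts rows by timestamp, and verifies that the
#' timestamps lie on a uniform grid (default cadence 20 minutes). Empty
#' cells and `"NaN"` are treated as missing.
#'
#' @param path Path to a CSV file.
#' @param timestamp_col Name of the timestamp column. Default `"timestamp"`.
#' @param tz Timezone used to parse ISO-8601 timestamps. Default `"UTC"`.
#' @return A tibble with a POSIXct `timestamp` column followed by numeric
#'   channel columns; missing observations are `NA`.
#' @export
read_series <- function(path, timestamp_col = "timestamp", tz = "UTC") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "NaN", "nan"))
  if (nrow(raw) == 0L) {
    stop("empty series file: ", path, call. = FALSE)
  }
  if (!timestamp_col %in% names(raw)) {
    stop("timestamp column '", timestamp_col, "' not found in ", path, call. = FALSE)
  }
  ts <- as.POSIXct(raw[[timestamp_col]], tz = tz)
  if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
  ord <- order(ts)
  raw <- raw[ord, , drop = FALSE]
  ts <- ts[ord]
  check_uniform_spacing(ts)
  channels <- setdiff(names(raw), timestamp_col)
  out <- tibble::as_tibble(raw[channels])
  out[] <- lapply(out, as.numeric)
  dplyr::bind_cols(tibble::tibble(timestamp = ts), out)
}

check_uniform_spacing <- function(ts) {
  if (length(ts) < 2L) return(invisible(TRUE))
  d <- as.numeric(diff(ts), units = "mins")
  bad <- which(abs(d - d[1L]) > 1e-6)
  if (length(bad)) {
    stop(sprintf(
      "nonuniform spacing: gap of %.6g min between rows %d and %d (expected %.6g min)",
      d[bad[1L]], bad[1L], bad[1L] + 1L, d[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

series_interval_minutes <- function(series) {
  ts <- series$timestamp
  if (length(ts) < 2L) return(NA_real_)
  as.numeric(ts[2L] - ts[1L], units = "mins")
}

series_channels <- function(series) setdiff(names(series), "timestamp")

#' Fill missing observations by linear interpolation
#'
#' Interior gaps in each channel are filled linearly between the nearest
#' observed neighbours; leading and trailing gaps take the nearest observed
#' value. Requires at least two observed values per channel.
#'
#' @param series A series tibble as returned by [read_series()].
#' @return The series with all `NA` cells filled.
#' @export
fill_missing_linear <- function(series) {
  chs <- series_channels(series)
  n <- nrow(series)
  for (ch in chs) {
    x <- series[[ch]]
    obs <- which(!is.na(x))
    if (length(obs) == 0L) {
      stop("channel '", ch, "' is entirely missing", call. = FALSE)
    }
    if (length(obs) < 2L) {
      stop("channel '", ch, "' has fewer than 2 observed values", call. = FALSE)
    }
    if (length(obs) < n) {
      series[[ch]] <- stats::approx(obs, x[obs], xout = seq_len(n),
                                    method = "linear", rule = 2)$y
    }
  }
  series
}

#' Fit min-max scaling statistics
#'
#' Records per-channel minimum and maximum, normally on the training
#' partition only so that no information from validation or test rows leaks
#' into the scaling. The scaled value is `(x - xmin) / (xmax - xmin)`.
#'
#' @param series A series tibble (typically the training rows only).
#' @param channels Channels to fit; default all non-timestamp columns.
#' @return An object of class `minmax_stats`: a tibble with columns
#'   `channel`, `xmin`, `xmax`.
#' @export
fit_minmax <- function(series, channels = NULL) {
  if (is.null(channels)) channels <- series_channels(series)
  xmin <- vapply(channels, function(ch) min(series[[ch]], na.rm = TRUE), 0)
  xmax <- vapply(channels, function(ch) max(series[[ch]], na.rm = TRUE), 0)
  const <- channels[xmax <= xmin]
  if (length(const)) {
    stop("constant channel(s) cannot be min-max scaled: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  structure(tibble::tibble(channel = channels, xmin = unname(xmin),
                           xmax = unname(xmax)),
            class = c("minmax_stats", class(tibble::tibble())))
}

#' Apply min-max scaling
#'
#' @param series A series tibble.
#' @param stats A `minmax_stats` object from [fit_minmax()].
#' @return The series with fitted channels scaled to `(x - xmin)/(xmax - xmin)`.
#' @export
scale_minmax <- function(series, stats) {
  for (i in seq_len(nrow(stats))) {
    ch <- stats$channel[i]
    if (!ch %in% names(series)) next
    series[[ch]] <- (series[[ch]] - stats$xmin[i]) / (stats$xmax[i] - stats$xmin[i])
  }
  series
}

#' Invert min-max scaling
#'
#' @param x A scaled numeric vector/matrix, or a scaled series tibble.
#' @param stats A `minmax_stats` object.
#' @param channel Channel whose statistics to use when `x` is numeric.
#' @return `x` mapped back to original units.
#' @export
invert_minmax <- function(x, stats, channel = NULL) {
  if (is.data.frame(x)) {
    for (i in seq_len(nrow(stats))) {
      ch <- stats$channel[i]
      if (!ch %in% names(x)) next
      x[[ch]] <- x[[ch]] * (stats$xmax[i] - stats$xmin[i]) + stats$xmin[i]
    }
    return(x)
  }
  stopifnot(!is.null(channel))
  i <- match(channel, stats$channel)
  if (is.na(i)) stop("no scaling statistics for channel '", channel, "'", call. = FALSE)
  x * (stats$xmax[i] - stats$xmin[i]) + stats$xmin[i]
}

#' Normalization range of a channel
#'
#' The range `xmax - xmin` recorded for a channel; for the target channel
#' this is the normalization constant used by the interval width metrics.
#'
#' @param stats A `minmax_stats` object.
#' @param channel Channel name.
#' @return A positive scalar.
#' @export
minmax_range <- function(stats, channel) {
  i <- match(channel, stats$channel)
  if (is.na(i)) stop("no scaling statistics for channel '", channel, "'", call. = FALSE)
  stats$xmax[i] - stats$xmin[i]
}

#' Chronological train/validation/test split
#'
#' Resolves split fractions into counts with the rule `n_train =
#' floor(r_train * n)`, `n_val = ceiling(r_val * n)`, `n_test = n - n_train
#' - n_val`; the first block is the training set, so ordering stays strictly
#' chronological. For 5767 points at 70/15/15 this yields 4036/866/865.
#'
#' @param n Series length.
#' @param ratios Numeric vector of three fractions summing to 1.
#' @return An object of class `split_spec` with fields `n`, `ratios`,
#'   `n_train`, `n_val`, `n_test`.
#' @export
chronological_split <- function(n, ratios = c(0.70, 0.15, 0.15)) {
  stopifnot(length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1", call. = FALSE)
  if (n < 3 && any(ratios > 0 & ratios < 1)) stop("need n >= 3 to split", call. = FALSE)
  n_train <- as.integer(floor(ratios[1L] * n))
  n_val <- as.integer(ceiling(ratios[2L] * n))
  n_test <- as.integer(n - n_train - n_val)
  if (n_test < 0L || n_val < 0L || n_train < 0L) {
    stop("split ratios resolve to a negative partition size", call. = FALSE)
  }
  structure(list(n = as.integer(n), ratios = ratios, n_train = n_train,
                 n_val = n_val, n_test = n_test),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("chronological split of %d points: train %d / val %d / test %d\n",
              x$n, x$n_train, x$n_val, x$n_test))
  invisible(x)
}

#' Label series rows with their chronological partition
#'
#' @param series A series tibble.
#' @param spec A `split_spec` from [chronological_split()].
#' @return The series with an added `.partition` factor column
#'   (`train`/`val`/`test`).
#' @export
apply_split <- function(series, spec) {
  stopifnot(inherits(spec, "split_spec"), nrow(series) == spec$n)
  series$.partition <- factor(rep(c("train", "val", "test"),
                                  times = c(spec$n_train, spec$n_val, spec$n_test)),
                              levels = c("train", "val", "test"))
  series
}

#' Window a series into supervised samples for direct multi-step forecasting
#'
#' Sample `i` (1-based) uses rows `[i, i + lookback)` as history and rows
#' `[i + lookback, i + lookback + horizon)` as the future targets, giving
#' `n - lookback - horizon + 1` strictly chronological windows.
#'
#' @param series A (scaled, gap-free) series tibble.
#' @param target Name of the target channel.
#' @param covariates Character vector of covariate channel names (possibly
#'   empty).
#' @param lookback History length T0 (steps), >= 1.
#' @param horizon Forecast horizon H (steps), >= 1.
#' @return An object of class `window_set`: a list with history-target
#'   matrix `X` (windows x lookback), flattened covariate matrix `Z`
#'   (windows x lookback*d), future-target matrix `C` (windows x horizon),
#'   plus bookkeeping fields.
#' @export
make_windows <- function(series, target, covariates = character(),
                         lookback, horizon) {
  stopifnot(lookback >= 1, horizon >= 1)
  n <- nrow(series)
  if (n < lookback + horizon) {
    stop(sprintf("series of length %d is too short for lookback %d + horizon %d",
                 n, lookback, horizon), call. = FALSE)
  }
  if (!target %in% names(series)) stop("unknown target channel '", target, "'", call. = FALSE)
  missing_cov <- setdiff(covariates, names(series))
  if (length(missing_cov)) {
    stop("unknown covariate channel(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  n_w <- n - lookback - horizon + 1L
  starts <- seq_len(n_w)
  y <- series[[target]]
  hist_idx <- outer(starts - 1L, seq_len(lookback), `+`)   # rows of history
  fut_idx <- outer(starts - 1L + lookback, seq_len(horizon), `+`)
  X <- matrix(y[hist_idx], nrow = n_w)
  C <- matrix(y[fut_idx], nrow = n_w)
  d <- length(covariates)
  if (d > 0L) {
    Z <- matrix(0, n_w, lookback * d)
    for (j in seq_len(d)) {
      Z[, (j - 1L) * lookback + seq_len(lookback)] <-
        matrix(series[[covariates[j]]][hist_idx], nrow = n_w)
    }
  } else {
    Z <- matrix(0, n_w, 0L)
  }
  structure(list(X = X, Z = Z, C = C,
                 target = target, covariates = covariates,
                 lookback = as.integer(lookback), horizon = as.integer(horizon),
                 start_timestamp = series$timestamp[starts]),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d samples, lookback %d, horizon %d, %d covariate(s)\n",
              nrow(x$X), x$lookback, x$horizon, length(x$covariates)))
  invisible(x)
}

# Subset a window_set by sample index.
windows_subset <- function(w, idx) {
  w$X <- w$X[idx, , drop = FALSE]
  w$Z <- w$Z[idx, , drop = FALSE]
  w$C <- w$C[idx, , drop = FALSE]
  w$start_timestamp <- w$start_timestamp[idx]
  w
}

#' Serialize scaling statistics to a JSON sidecar
#'
#' @param stats A `minmax_stats` object.
#' @param path Output path.
#' @export
write_minmax <- function(stats, path) {
  jsonlite::write_json(as.data.frame(stats), path, digits = NA)
  invisible(path)
}

#' Read scaling statistics from a JSON sidecar
#'
#' @param path Path written by [write_minmax()].
#' @return A `minmax_stats` object.
#' @export
read_minmax <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(tibble::as_tibble(df), class = c("minmax_stats", class(tibble::tibble())))
}
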