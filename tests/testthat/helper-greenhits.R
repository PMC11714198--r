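# Shared fixtures, all built in code.

# A tiny uniform series tibble with the given channel vectors.
tiny_series <- function(..., interval_minutes = 20) {
  ch <- list(...)
  n <- length(ch[[1L]])
  tibble::tibble(
    timestamp = as.POSIXct("2024-02-14 00:00:00", tz = "UTC") +
      (seq_len(n) - 1L) * interval_minutes * 60,
    !!!ch)
}

# Write a series tibble to a temporary CSV in the package's dialect.
write_series_csv <- function(series, path = tempfile(fileext = ".csv")) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

# Small scaled window sets from a simulated series, for model tests.
sim_windows <- function(n_days = 14, lookback = 8, horizon = 3, seed = 1,
                        covariates = "air_temperature", ...) {
  series <- simulate_greenhouse(sim_config(n_days = n_days, seed = seed, ...))
  split <- chronological_split(nrow(series))
  tr <- series[seq_len(split$n_train), ]
  va <- series[split$n_train + seq_len(split$n_val), ]
  te <- series[split$n_train + split$n_val + seq_len(split$n_test), ]
  sc <- fit_minmax(tr)
  list(
    train = make_windows(scale_minmax(tr, sc), "soil_temperature", covariates,
                         lookback, horizon),
    val = make_windows(scale_minmax(va, sc), "soil_temperature", covariates,
                       lookback, horizon),
    test = make_windows(scale_minmax(te, sc), "soil_temperature", covariates,
                        lookback, horizon),
    scaler = sc, split = split, series = series)
}
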