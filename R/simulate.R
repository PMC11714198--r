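#' Configuration for the synthetic greenhouse generator
#'
#' Describes a greenhouse-like multivariate series: each channel is a
#' diurnal sinusoid plus stationary AR(1) noise, and the soil-temperature
#' channel is additionally coupled to the air-temperature channel at a
#' configurable lag (soil temperature follows air temperature after about
#' two hours at the default 20-minute cadence). Pure-noise channels and
#' uniformly injected missing values make feature selection and gap repair
#' testable without any external data.
#'
#' @param n_days Length of the series in days (default 80, roughly a
#'   late-winter-to-spring greenhouse campaign).
#' @param interval_minutes Sampling cadence in minutes (default 20).
#' @param channels A data frame with columns `channel`, `mean`, `amp`,
#'   `phase`, `rho`, `sd` (per-channel sinusoid and AR(1) noise settings, in
#'   channel units). Defaults emulate the seven-sensor greenhouse suite.
#' @param beta Coupling coefficient from lagged air temperature deviation
#'   into soil temperature (unitless, default 0.35).
#' @param lag Coupling lag in steps (default 6 = 2 h at 20-minute cadence).
#' @param n_noise_channels Number of additional pure-noise channels
#'   (default 0).
#' @param missing_rate Fraction of cells set to missing, uniformly at
#'   random per channel (default 0).
#' @param start Timestamp of the first observation.
#' @param seed Master seed; per-channel RNG streams are derived from it and
#'   the channel name, so adding channels never perturbs existing ones.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_days = 80,
                       interval_minutes = 20,
                       channels = default_sim_channels(),
                       beta = 0.35,
                       lag = 6L,
                       n_noise_channels = 0L,
                       missing_rate = 0,
                       start = as.POSIXct("2024-02-14 00:00:00", tz = "UTC"),
                       seed = 1L) {
  stopifnot(n_days >= 1, interval_minutes > 0)
  channels <- tibble::as_tibble(channels)
  needed <- c("channel", "mean", "amp", "phase", "rho", "sd")
  if (!all(needed %in% names(channels))) {
    stop("channels table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(channels$channel)) stop("duplicate channel names", call. = FALSE)
  if (any(channels$amp < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(channels$rho < 0 | channels$rho >= 1)) stop("ar1 rho must be in [0, 1)", call. = FALSE)
  if (any(channels$sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  if (!all(c("soil_temperature", "air_temperature") %in% channels$channel) && beta != 0) {
    stop("coupling requires soil_temperature and air_temperature channels", call. = FALSE)
  }
  structure(list(n_days = n_days, interval_minutes = interval_minutes,
                 channels = channels, beta = beta, lag = as.integer(lag),
                 n_noise_channels = as.integer(n_noise_channels),
                 missing_rate = missing_rate, start = start,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-channel settings of the synthetic greenhouse
#'
#' Means, diurnal amplitudes, phases and AR(1) noise levels chosen to look
#' like a heated foliage-plant greenhouse: air temperature swings several
#' degrees over the day, soil temperature is smoother and damped, humidity
#' moves against temperature, and light follows the day cycle.
#'
#' @return A tibble with one row per channel.
#' @export
default_sim_channels <- function() {
  tibble::tribble(
    ~channel,            ~mean, ~amp, ~phase,   ~rho, ~sd,
    "soil_temperature",    20,   1.5, -0.9,     0.70, 0.25,
    "air_temperature",     22,   5.0, -0.5,     0.80, 0.60,
    "air_humidity",        70,  12.0,  2.64,    0.80, 2.00,
    "soil_moisture",       45,   1.0,  0.6,     0.90, 0.40,
    "light",              320, 300.0, -0.5,     0.60, 40.0,
    "soil_conductivity",  150,   4.0,  0.6,     0.90, 1.50,
    "carbon_dioxide",     450,  60.0,  2.64,    0.70, 15.0
  )
}

# Derived, order-independent per-channel seed (kept below 2^31).
channel_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

# Deterministic (noise-free) component of a channel at 0-based step t.
sim_deterministic <- function(t, mean, amp, phase, steps_per_day) {
  mean + amp * sin(2 * pi * t / steps_per_day + phase)
}

# Stationary AR(1) path of length n: e_t = rho e_{t-1} + N(0, sd^2).
ar1_path <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1L] <- rnorm(1L, 0, sd / sqrt(1 - rho^2))
  if (n > 1L) {
    eps <- rnorm(n - 1L, 0, sd)
    for (t in 2:n) e[t] <- rho * e[t - 1L] + eps[t - 1L]
  }
  e
}

#' Generate a synthetic greenhouse series
#'
#' Each channel is `mean + amp * sin(2*pi*t/steps_per_day + phase)` plus
#' stationary AR(1) noise; soil temperature additionally receives
#' `beta * (air_temperature(t - lag) - mean_air)`. Missing cells are then
#' injected uniformly at `missing_rate`. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return A series tibble in the [read_series()] layout, with `NA` for
#'   injected missing cells.
#' @export
simulate_greenhouse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spd <- 1440 / config$interval_minutes
  n <- as.integer(round(config$n_days * spd))
  pad <- config$lag                       # burn-in so the lagged term exists at t = 1
  tt <- seq_len(n + pad) - 1L - pad       # 0-based step index, first kept step is 0
  ch <- config$channels
  paths <- list()
  for (i in seq_len(nrow(ch))) {
    e <- local_seed(channel_seed(config$seed, ch$channel[i]),
                    ar1_path(n + pad, ch$rho[i], ch$sd[i]))
    paths[[ch$channel[i]]] <-
      sim_deterministic(tt, ch$mean[i], ch$amp[i], ch$phase[i], spd) + e
  }
  if (config$beta != 0 && "soil_temperature" %in% names(paths)) {
    air <- paths[["air_temperature"]]
    mean_air <- ch$mean[ch$channel == "air_temperature"]
    dev <- air - mean_air
    idx <- seq_len(n + pad) - config$lag
    lagged <- ifelse(idx >= 1L, dev[pmax(idx, 1L)], 0)
    paths[["soil_temperature"]] <- paths[["soil_temperature"]] + config$beta * lagged
  }
  keep <- (pad + 1L):(n + pad)
  out <- tibble::as_tibble(lapply(paths, function(p) p[keep]))
  if (config$n_noise_channels > 0L) {
    for (j in seq_len(config$n_noise_channels)) {
      nm <- paste0("noise_", j)
      out[[nm]] <- local_seed(channel_seed(config$seed, nm),
                              50 + ar1_path(n, 0.5, 1))
    }
  }
  if (config$missing_rate > 0) {
    for (nm in names(out)) {
      drop <- local_seed(channel_seed(config$seed + 1L, nm),
                         which(runif(n) < config$missing_rate))
      # keep at least two observed values so interpolation stays defined
      if (length(drop) > n - 2L) drop <- drop[seq_len(n - 2L)]
      out[[nm]][drop] <- NA_real_
    }
  }
  timestamp <- config$start + (seq_len(n) - 1L) * config$interval_minutes * 60
  dplyr::bind_cols(tibble::tibble(timestamp = timestamp), out)
}

#' Analytic forecast distribution of the synthetic generator
#'
#' The exact conditional distribution of the soil-temperature channel `h`
#' steps ahead given the generated history: the oracle against which
#' learned predictive distributions are judged. Requires `lag >= horizon`
#' when the air-to-soil coupling is active, so that the coupling term is
#' observed rather than itself random.
#'
#' @param config The [sim_config()] that generated the series.
#' @param history A gap-free series tibble holding at least `lag + 1` rows
#'   of generated history, ending at the forecast origin.
#' @param horizon Number of steps ahead.
#' @return A tibble of class `gaussian_forecast` with columns `step`, `mu`,
#'   `sigma` (channel units).
#' @export
true_forecast_distribution <- function(config, history, horizon) {
  stopifnot(inherits(config, "sim_config"), horizon >= 1)
  ch <- config$channels
  soil <- ch[ch$channel == "soil_temperature", ]
  air <- ch[ch$channel == "air_temperature", ]
  if (config$beta != 0 && config$lag < horizon) {
    stop("analytic oracle requires lag >= horizon when beta != 0", call. = FALSE)
  }
  spd <- 1440 / config$interval_minutes
  n_hist <- nrow(history)
  if (n_hist < config$lag + 1L) stop("history shorter than lag + 1", call. = FALSE)
  # absolute 0-based step index of each history row, from the timestamps
  t0 <- as.numeric(difftime(history$timestamp[n_hist], config$start, units = "mins")) /
    config$interval_minutes
  if (abs(t0 - round(t0)) > 1e-6) stop("history timestamps off the generator grid", call. = FALSE)
  t0 <- round(t0)
  det_soil <- function(t) sim_deterministic(t, soil$mean, soil$amp, soil$phase, spd)
  # recover the soil AR(1) state at the forecast origin
  coup0 <- 0
  if (config$beta != 0) {
    air_lag_val <- history$air_temperature[n_hist - config$lag]
    coup0 <- config$beta * (air_lag_val - air$mean)
  }
  e_t <- history$soil_temperature[n_hist] - det_soil(t0) - coup0
  steps <- seq_len(horizon)
  mu <- sigma <- numeric(horizon)
  for (h in steps) {
    coup <- 0
    if (config$beta != 0) {
      air_obs <- history$air_temperature[n_hist + h - config$lag]
      coup <- config$beta * (air_obs - air$mean)
    }
    mu[h] <- det_soil(t0 + h) + coup + soil$rho^h * e_t
    sigma[h] <- soil$sd * sqrt(sum(soil$rho^(2 * (0:(h - 1)))))
  }
  structure(tibble::tibble(step = steps, mu = mu, sigma = sigma),
            class = c("gaussian_forecast", class(tibble::tibble())))
}

#' Write a simulated series and its configuration to disk
#'
#' @param config A [sim_config()].
#' @param csv_path Output CSV path (series, [read_series()] dialect).
#' @param config_path Optional JSON path for the configuration.
#' @return The generated series, invisibly.
#' @export
write_simulation <- function(config, csv_path, config_path = NULL) {
  series <- simulate_greenhouse(config)
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  if (!is.null(config_path)) {
    cfg <- config
    cfg$start <- format(cfg$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    cfg$channels <- as.data.frame(cfg$channels)
    jsonlite::write_json(unclass(cfg), config_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(series)
}
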