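#' Pipeline configuration
#'
#' Declarative description of an end-to-end run: data source, target and
#' covariates, window geometry, split, interval method, optimizer settings,
#' and the master seed. Every field mirrors a key of the YAML/JSON config
#' accepted by the command-line wrapper.
#'
#' @param input Path to a sensor CSV, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param target Target channel (default `"soil_temperature"`).
#' @param covariates Covariate channels; `NULL` selects them by
#'   gradient-boosted ranking plus backward elimination.
#' @param lookback History length T0 (ignored when the optimizer runs and
#'   searches it).
#' @param horizons Horizons to train and evaluate (default `c(1, 3, 6)`,
#'   i.e. 20/60/120 minutes at 20-minute cadence).
#' @param ratios Chronological split fractions (default 0.70/0.15/0.15).
#' @param interval_method `"gaussian"`, `"error_fit"`, `"bootstrap"`, or
#'   `"quantile"`.
#' @param level Interval confidence level (default 0.90).
#' @param select_features Run feature selection? (default `TRUE`).
#' @param optimize Run SMPSO hyperparameter search? (default `FALSE`).
#' @param optimizer List of SMPSO settings: `swarm_size`, `iterations`,
#'   `capacity`, `max_epochs`, `patience`, `n_samples`.
#' @param model List of [nhits_config()] overrides for the final fit
#'   (e.g. `mlp_units`, `max_epochs`, `patience`).
#' @param n_samples Monte-Carlo draws for the final intervals (default 500).
#' @param seed Master seed.
#' @param out_dir Directory for artifacts (JSON reports, forecast CSV), or
#'   `NULL` to keep results in memory only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            target = "soil_temperature", covariates = NULL,
                            lookback = 12L, horizons = c(1L, 3L, 6L),
                            ratios = c(0.70, 0.15, 0.15),
                            interval_method = c("gaussian", "error_fit",
                                                "bootstrap", "quantile"),
                            level = 0.90, select_features = TRUE,
                            optimize = FALSE,
                            optimizer = list(), model = list(),
                            n_samples = 500L, seed = 1L, out_dir = NULL) {
  interval_method <- match.arg(interval_method)
  opt_defaults <- list(swarm_size = 20L, iterations = 25L, capacity = 50L,
                       max_epochs = 150L, patience = 50L, n_samples = 200L)
  structure(list(input = input, sim = sim, target = target,
                 covariates = covariates, lookback = as.integer(lookback),
                 horizons = as.integer(horizons), ratios = ratios,
                 interval_method = interval_method, level = level,
                 select_features = select_features, optimize = optimize,
                 optimizer = utils::modifyList(opt_defaults, optimizer),
                 model = model, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end forecasting pipeline
#'
#' Executes preprocess (gap repair, chronological split, min-max scaling
#' fitted on the training block) -> feature selection -> optional SMPSO
#' hyperparameter optimization -> per-horizon training -> test-set
#' evaluation -> a forecast beyond the end of the series, and returns all
#' artifacts. With `out_dir` set, each stage also writes its artifact and a
#' manifest records the configuration and seeds.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `series`, `split`, `scaler`,
#'   `selection`, `optimization`, and a per-horizon list `runs` each holding
#'   the fitted model, metrics tibble and forecast tibble; plus `metrics`, a
#'   combined tibble over horizons.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  series <- pipeline_stage("data", {
    if (!is.null(config$input)) read_series(config$input)
    else simulate_greenhouse(config$sim)
  })
  chs <- series_channels(series)
  if (!config$target %in% chs) {
    stop("pipeline stage 'validate' failed: target channel '", config$target,
         "' not in series", call. = FALSE)
  }
  if (!is.null(config$covariates)) {
    miss <- setdiff(config$covariates, chs)
    if (length(miss)) {
      stop("pipeline stage 'validate' failed: unknown covariate(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  series <- pipeline_stage("preprocess", fill_missing_linear(series))
  split <- pipeline_stage("split", chronological_split(nrow(series), config$ratios))
  tr_rows <- seq_len(split$n_train)
  va_rows <- split$n_train + seq_len(split$n_val)
  te_rows <- split$n_train + split$n_val + seq_len(split$n_test)
  scaler <- pipeline_stage("scale", fit_minmax(series[tr_rows, ]))
  scaled <- scale_minmax(series, scaler)

  selection <- NULL
  covariates <- config$covariates
  if (is.null(covariates)) {
    if (config$select_features) {
      selection <- pipeline_stage("select_features", {
        sup <- lag_supervise(scaled[tr_rows, ], config$target, lag = 1L)
        backward_eliminate(sup$features, sup$target, seed = config$seed)
      })
      covariates <- setdiff(lagged_to_channels(selection$best_features),
                            config$target)
    } else {
      covariates <- setdiff(chs, config$target)
    }
  }

  optimization <- NULL
  chosen <- NULL
  if (isTRUE(config$optimize)) {
    optimization <- pipeline_stage("optimize", {
      opt <- config$optimizer
      horizon_opt <- max(config$horizons)
      smpso_optimize(
        function(hp) evaluate_candidate(
          hp, scaled[tr_rows, ], scaled[va_rows, ], config$target, covariates,
          horizon = horizon_opt, range_a = 1, level = config$level,
          max_epochs = opt$max_epochs, patience = opt$patience,
          n_samples = opt$n_samples, seed = config$seed),
        search_space(), swarm_size = opt$swarm_size,
        iterations = opt$iterations, capacity = opt$capacity,
        seed = config$seed)
    })
    chosen <- select_final(optimization)
  }

  range_a <- minmax_range(scaler, config$target)
  runs <- list()
  for (H in config$horizons) {
    runs[[as.character(H)]] <- pipeline_stage(paste0("train_h", H), {
      run_one_horizon(config, scaled, tr_rows, va_rows, te_rows, covariates,
                      chosen, H, scaler, range_a)
    })
  }
  metrics <- dplyr::bind_rows(lapply(runs, `[[`, "metrics"))
  result <- structure(list(config = config, series = series, split = split,
                           scaler = scaler, selection = selection,
                           covariates = covariates,
                           optimization = optimization,
                           chosen_hyperparameters = chosen,
                           runs = runs, metrics = metrics),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) pipeline_stage("write", write_artifacts(result))
  result
}

# Train, evaluate and forecast for a single horizon.
run_one_horizon <- function(config, scaled, tr_rows, va_rows, te_rows,
                            covariates, chosen, H, scaler, range_a) {
  lookback <- if (!is.null(chosen)) as.integer(chosen[["lookback"]]) else config$lookback
  base_args <- list(lookback = lookback, horizon = as.integer(H),
                    level = config$level, seed = config$seed)
  if (!is.null(chosen)) {
    base_args$n_blocks <- chosen[["n_blocks"]]
    base_args$mlp_units <- chosen[["mlp_units"]]
    base_args$n_pool_kernel_size <- chosen[["n_pool_kernel_size"]]
    base_args$n_freq_downsample <- chosen[["n_freq_downsample"]]
  }
  base_args$loss <- switch(config$interval_method,
                           gaussian = "gaussian", quantile = "quantile",
                           "mae")
  cfg <- do.call(nhits_config, utils::modifyList(base_args, config$model))
  tr_w <- make_windows(scaled[tr_rows, ], config$target, covariates, lookback, H)
  va_w <- make_windows(scaled[va_rows, ], config$target, covariates, lookback, H)
  te_w <- make_windows(scaled[te_rows, ], config$target, covariates, lookback, H)
  fit <- fit_nhits(tr_w, va_w, cfg)

  calibrator <- NULL
  test_iv <- if (config$interval_method == "gaussian") {
    pred <- stats::predict(fit, te_w)
    mc_intervals(pred$mu, pred$sigma, n_samples = config$n_samples,
                 level = config$level, seed = config$seed)
  } else if (config$interval_method == "quantile") {
    stats::predict(fit, te_w)
  } else {
    va_pt <- stats::predict(fit, va_w)
    calibrator <- interval_from_errors(va_w$C - va_pt,
                                       method = config$interval_method,
                                       level = config$level, seed = config$seed)
    apply_calibrator(calibrator, stats::predict(fit, te_w))
  }
  # evaluate in original units
  to_orig <- function(m) invert_minmax(m, scaler, config$target)
  obs <- to_orig(te_w$C)
  med <- to_orig(test_iv$median)
  lo <- to_orig(test_iv$lower); up <- to_orig(test_iv$upper)
  metrics <- dplyr::bind_cols(
    tibble::tibble(horizon = H, method = config$interval_method),
    point_metrics(med, obs),
    interval_metrics(obs, lo, up, range_a = range_a))
  forecast <- forecast_next(fit, scaled, scaler, config,
                            calibrator = calibrator)
  list(model = fit, calibrator = calibrator, metrics = metrics,
       forecast = forecast)
}

#' Forecast beyond the end of a series
#'
#' Applies a fitted model to the final lookback window and returns the
#' interval forecast in original units, one row per horizon step, each
#' labelled with its future timestamp at the series cadence.
#'
#' @param model A fitted `nhits_model`.
#' @param scaled The full scaled series tibble (only the last `lookback`
#'   rows are used).
#' @param scaler The `minmax_stats` used to scale the series.
#' @param config The `pipeline_config` (level, Monte-Carlo draws, seed).
#' @param calibrator Optional `interval_calibrator` for the residual-based
#'   methods.
#' @return A tibble with columns `timestamp`, `step`, `lower`, `median`,
#'   `upper`, `level` in original target units.
#' @export
forecast_next <- function(model, scaled, scaler, config, calibrator = NULL) {
  T0 <- model$config$lookback; H <- model$config$horizon
  n <- nrow(scaled)
  if (n < T0) stop("series shorter than the model lookback", call. = FALSE)
  tail_rows <- scaled[(n - T0 + 1L):n, ]
  X <- matrix(tail_rows[[model$target]], nrow = 1L)
  d <- length(model$covariates)
  Z <- if (d > 0L) {
    matrix(unlist(lapply(model$covariates, function(ch) tail_rows[[ch]])),
           nrow = 1L)
  } else matrix(0, 1L, 0L)
  w <- structure(list(X = X, Z = Z, C = matrix(NA_real_, 1L, H),
                      lookback = T0, horizon = H,
                      target = model$target, covariates = model$covariates),
                 class = "window_set")
  iv <- if (model$config$loss == "gaussian") {
    pred <- stats::predict(model, w)
    mc_intervals(pred$mu, pred$sigma, n_samples = config$n_samples,
                 level = config$level, seed = config$seed)
  } else if (model$config$loss == "quantile") {
    stats::predict(model, w)
  } else {
    if (is.null(calibrator)) stop("point model needs an interval calibrator", call. = FALSE)
    apply_calibrator(calibrator, stats::predict(model, w))
  }
  step_min <- series_interval_minutes(scaled)
  tibble::tibble(
    timestamp = scaled$timestamp[n] + seq_len(H) * step_min * 60,
    step = seq_len(H),
    lower = invert_minmax(as.numeric(iv$lower), scaler, model$target),
    median = invert_minmax(as.numeric(iv$median), scaler, model$target),
    upper = invert_minmax(as.numeric(iv$upper), scaler, model$target),
    level = config$level)
}

# Write pipeline artifacts and a manifest under config$out_dir.
write_artifacts <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(result$config$out_dir, f)
  write_minmax(result$scaler, p("scaling.json"))
  jsonlite::write_json(as.data.frame(result$metrics), p("metrics.json"),
                       digits = NA)
  if (!is.null(result$selection)) {
    jsonlite::write_json(list(
      ranking = as.data.frame(result$selection$ranking),
      best_features = result$selection$best_features,
      trace = lapply(seq_len(nrow(result$selection$trace)), function(i)
        list(n_features = result$selection$trace$n_features[i],
             features = result$selection$trace$features[[i]],
             rmse = result$selection$trace$rmse[i]))),
      p("feature_selection.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$optimization)) {
    jsonlite::write_json(list(
      positions = result$optimization$archive$positions,
      objectives = result$optimization$archive$objectives,
      selected = as.list(result$chosen_hyperparameters)),
      p("optimization.json"), auto_unbox = TRUE, digits = NA)
  }
  fc <- dplyr::bind_rows(lapply(names(result$runs), function(h) {
    dplyr::mutate(result$runs[[h]]$forecast, horizon = as.integer(h))
  }))
  fc$timestamp <- format(fc$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(fc, p("forecast.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("greenhits")),
    r_version = as.character(getRversion()),
    seed = result$config$seed,
    target = result$config$target,
    covariates = result$covariates,
    horizons = result$config$horizons,
    interval_method = result$config$interval_method,
    level = result$config$level,
    split = result$split[c("n", "n_train", "n_val", "n_test")])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("greenhouse forecasting pipeline result\n")
  print(x$split)
  cat("covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  cat("test metrics:\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 4)
  invisible(x)
}
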