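#' Save a fitted N-HiTS model as JSON
#'
#' Serializes the configuration, all block parameters, and (optionally) the
#' scaling statistics to a plain-text JSON checkpoint, so a model can be
#' reloaded later and its forecasts reported in original units.
#'
#' @param model A fitted `nhits_model`.
#' @param path Output path.
#' @param scaler Optional `minmax_stats` to store alongside the model.
#' @return `path`, invisibly.
#' @export
save_nhits_model <- function(model, path, scaler = NULL) {
  stopifnot(inherits(model, "nhits_model"))
  pack_mat <- function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(dim = NULL, data = as.numeric(m))
  }
  blocks <- lapply(model$blocks, function(blk) {
    list(stack = blk$stack, kernel = blk$kernel,
         W1 = pack_mat(blk$W1), b1 = pack_mat(blk$b1),
         W2 = pack_mat(blk$W2), b2 = pack_mat(blk$b2),
         Wb = pack_mat(blk$Wb), bb = pack_mat(blk$bb),
         Wf = lapply(blk$Wf, pack_mat), bf = lapply(blk$bf, pack_mat),
         Kn = blk$Kn)
  })
  payload <- list(
    config = unclass(model$config),
    target = model$target, covariates = model$covariates,
    z_dim = model$z_dim, best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    blocks = blocks,
    history = as.data.frame(model$history),
    scaler = if (!is.null(scaler)) as.data.frame(scaler))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a fitted N-HiTS model from JSON
#'
#' @param path A checkpoint written by [save_nhits_model()].
#' @return A list with elements `model` (an `nhits_model`) and `scaler`
#'   (a `minmax_stats` or `NULL`).
#' @export
read_nhits_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  cfg <- payload$config
  config <- nhits_config(
    lookback = cfg$lookback, horizon = cfg$horizon, n_stacks = cfg$n_stacks,
    n_blocks = cfg$n_blocks, mlp_units = cfg$mlp_units,
    n_pool_kernel_size = cfg$n_pool_kernel_size,
    n_freq_downsample = cfg$n_freq_downsample, loss = cfg$loss,
    level = cfg$level, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
    patience = cfg$patience, seed = cfg$seed)
  unpack_mat <- function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  }
  # fresh skeleton supplies the derived fields (groups, interp matrix)
  blocks <- init_nhits(config, payload$z_dim)
  stored <- payload$blocks
  n_ch <- n_output_channels(config$loss)
  for (j in seq_along(blocks)) {
    sj <- stored[[j]]
    for (nm in c("W1", "b1", "W2", "b2", "Wb", "bb")) {
      blocks[[j]][[nm]] <- unpack_mat(sj[[nm]])
    }
    for (c in seq_len(n_ch)) {
      blocks[[j]]$Wf[[c]] <- unpack_mat(sj$Wf[[c]])
      blocks[[j]]$bf[[c]] <- unpack_mat(sj$bf[[c]])
    }
  }
  model <- structure(list(
    config = config, blocks = blocks, best_epoch = payload$best_epoch,
    best_val_loss = payload$best_val_loss, z_dim = payload$z_dim,
    covariates = payload$covariates %||% character(),
    target = payload$target,
    history = dplyr::bind_rows(payload$history)),
    class = "nhits_model")
  scaler <- NULL
  if (!is.null(payload$scaler) && length(payload$scaler)) {
    scaler <- structure(dplyr::bind_rows(payload$scaler),
                        class = c("minmax_stats", class(tibble::tibble())))
  }
  list(model = model, scaler = scaler)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
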