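#' N-HiTS model configuration
#'
#' Architecture and training settings for the hierarchical-interpolation
#' forecaster. Each stack applies non-overlapping max pooling (its own
#' kernel) to the target history, runs `n_blocks` MLP blocks that emit a
#' full-resolution backcast and a coarse set of forecast knots
#' (`max(ceiling(horizon / n_freq_downsample), 1)` of them), and the knots
#' are up-sampled to the horizon by linear interpolation. Blocks are chained
#' by residual subtraction of backcasts from the target history; the model
#' forecast is the sum of all block forecasts.
#'
#' @param lookback History length T0 in steps.
#' @param horizon Forecast horizon H in steps.
#' @param n_stacks Number of stacks (default 3).
#' @param n_blocks Blocks per stack; scalar or length-`n_stacks` vector.
#' @param mlp_units Hidden width of each block's 2-layer ReLU MLP.
#' @param n_pool_kernel_size Per-stack max-pool kernel; scalar or vector.
#' @param n_freq_downsample Per-stack downsample factor for forecast knots;
#'   scalar or vector.
#' @param loss `"mae"` (point), `"gaussian"` (mean + scale head trained by
#'   Gaussian negative log-likelihood), or `"quantile"` (three pinball-loss
#'   heads at the interval quantiles).
#' @param level Confidence level for interval-producing losses (default 0.90).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Training epoch cap (default 500).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 50).
#' @param seed Seed controlling initialization and batch shuffling.
#' @return An object of class `nhits_config`.
#' @export
nhits_config <- function(lookback = 12L, horizon = 6L,
                         n_stacks = 3L, n_blocks = 1L,
                         mlp_units = 128L,
                         n_pool_kernel_size = c(4L, 2L, 2L),
                         n_freq_downsample = c(4L, 2L, 1L),
                         loss = c("mae", "gaussian", "quantile"),
                         level = 0.90,
                         learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 500L, patience = 50L, seed = 1L) {
  loss <- match.arg(loss)
  rep_stack <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) rep(x, n_stacks)
    else if (length(x) == n_stacks) x
    else if (length(x) > n_stacks) x[seq_len(n_stacks)]
    else stop("per-stack setting has wrong length", call. = FALSE)
  }
  n_stacks <- as.integer(n_stacks)
  stopifnot(lookback >= 1, horizon >= 1, n_stacks >= 1, mlp_units >= 1,
            level > 0, level < 1, learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  cfg <- list(lookback = as.integer(lookback), horizon = as.integer(horizon),
              n_stacks = n_stacks,
              n_blocks = rep_stack(n_blocks),
              mlp_units = as.integer(mlp_units),
              n_pool_kernel_size = rep_stack(n_pool_kernel_size),
              n_freq_downsample = rep_stack(n_freq_downsample),
              loss = loss, level = level,
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              seed = as.integer(seed))
  if (any(cfg$n_blocks < 1) || any(cfg$n_pool_kernel_size < 1) ||
      any(cfg$n_freq_downsample < 1)) {
    stop("n_blocks, pool kernels and downsample factors must be >= 1", call. = FALSE)
  }
  class(cfg) <- "nhits_config"
  cfg
}

n_output_channels <- function(loss) switch(loss, mae = 1L, gaussian = 2L, quantile = 3L)

#' Non-overlapping max pooling of a history window
#'
#' Max pooling with stride equal to the kernel; the last window may be
#' partial (ceiling padding), so the output length is `ceiling(n / k)`.
#' Kernel 1 is the identity.
#'
#' @param x Numeric vector, or matrix pooled along rows.
#' @param k Kernel size (>= 1).
#' @return Pooled vector (or matrix with `ceiling(ncol(x)/k)` columns).
#' @export
multirate_pool <- function(x, k) {
  if (k < 1) stop("pooling kernel must be >= 1", call. = FALSE)
  if (is.matrix(x)) {
    groups <- pool_groups(ncol(x), k)
    out <- matrix(0, nrow(x), length(groups))
    for (g in seq_along(groups)) {
      sub <- x[, groups[[g]], drop = FALSE]
      out[, g] <- if (ncol(sub) == 1L) sub[, 1L] else do.call(pmax, asplit(sub, 2L))
    }
    out
  } else {
    groups <- pool_groups(length(x), k)
    unname(vapply(groups, function(g) max(x[g]), 0))
  }
}

pool_groups <- function(n, k) {
  k <- as.integer(k)
  split(seq_len(n), ceiling(seq_len(n) / k))
}

#' Linear interpolation matrix from forecast knots to the full horizon
#'
#' Maps `n_knots` equally spaced knots (endpoints pinned to the first and
#' last horizon step) to `horizon` values by linear interpolation. With
#' `n_knots == horizon` this is the identity; with a single knot the
#' forecast is constant.
#'
#' @param horizon Horizon length H.
#' @param n_knots Number of knots.
#' @return A `horizon x n_knots` matrix `M` such that `forecast = M %*% knots`.
#' @export
interp_matrix <- function(horizon, n_knots) {
  stopifnot(horizon >= 1, n_knots >= 1)
  if (n_knots == 1L) return(matrix(1, horizon, 1L))
  p <- seq(1, horizon, length.out = n_knots)
  M <- matrix(0, horizon, n_knots)
  for (j in seq_len(n_knots)) {
    e <- numeric(n_knots); e[j] <- 1
    M[, j] <- stats::approx(p, e, xout = seq_len(horizon))$y
  }
  M
}

knot_count <- function(horizon, d) max(ceiling(horizon / d), 1L)

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Initialize the full parameter set. Forecast heads start at zero so the
# initial model predicts 0 and residual contributions grow from nothing.
init_nhits <- function(config, z_dim) {
  T0 <- config$lookback; H <- config$horizon
  n_ch <- n_output_channels(config$loss)
  u <- config$mlp_units
  blocks <- list()
  for (s in seq_len(config$n_stacks)) {
    k <- min(config$n_pool_kernel_size[s], T0)
    groups <- pool_groups(T0, k)
    Lp <- length(groups)
    Kn <- knot_count(H, config$n_freq_downsample[s])
    M <- interp_matrix(H, Kn)
    in_dim <- Lp + z_dim
    for (b in seq_len(config$n_blocks[s])) {
      blk <- list(
        stack = s, kernel = k, groups = groups, Lp = Lp, M = M, Kn = Kn,
        W1 = glorot(in_dim, u), b1 = numeric(u),
        W2 = glorot(u, u), b2 = numeric(u),
        Wb = glorot(u, T0) * 0.1, bb = numeric(T0),
        Wf = lapply(seq_len(n_ch), function(i) matrix(0, u, Kn)),
        bf = lapply(seq_len(n_ch), function(i) numeric(Kn)))
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  blocks
}

pool_forward <- function(R, groups) {
  B <- nrow(R)
  Lp <- length(groups)
  P <- matrix(0, B, Lp)
  amax <- matrix(1L, B, Lp)
  for (g in seq_len(Lp)) {
    cols <- groups[[g]]
    if (length(cols) == 1L) {
      P[, g] <- R[, cols]
    } else {
      sub <- R[, cols, drop = FALSE]
      am <- max.col(sub, ties.method = "first")
      amax[, g] <- am
      P[, g] <- sub[cbind(seq_len(B), am)]
    }
  }
  list(P = P, amax = amax)
}

# Forward pass over all blocks. Returns per-channel forecast sums and,
# when keep_cache, the intermediates needed for backprop.
nhits_forward_pass <- function(blocks, config, X, Z, keep_cache = FALSE,
                               collect_blocks = FALSE) {
  B <- nrow(X); H <- config$horizon
  n_ch <- n_output_channels(config$loss)
  R <- X
  Ftot <- lapply(seq_len(n_ch), function(i) matrix(0, B, H))
  Fblocks <- if (collect_blocks) vector("list", length(blocks)) else NULL
  cache <- if (keep_cache) vector("list", length(blocks)) else NULL
  add_bias <- function(S, b) sweep(S, 2L, b, `+`)
  for (j in seq_along(blocks)) {
    blk <- blocks[[j]]
    pf <- pool_forward(R, blk$groups)
    A0 <- cbind(pf$P, Z)
    S1 <- add_bias(A0 %*% blk$W1, blk$b1); H1 <- S1 * (S1 > 0)
    S2 <- add_bias(H1 %*% blk$W2, blk$b2); H2 <- S2 * (S2 > 0)
    Bc <- add_bias(H2 %*% blk$Wb, blk$bb)
    Fb <- vector("list", n_ch)
    for (c in seq_len(n_ch)) {
      K <- add_bias(H2 %*% blk$Wf[[c]], blk$bf[[c]])
      Fc <- K %*% t(blk$M)
      Ftot[[c]] <- Ftot[[c]] + Fc
      Fb[[c]] <- Fc
    }
    if (collect_blocks) Fblocks[[j]] <- Fb
    if (keep_cache) cache[[j]] <- list(amax = pf$amax, A0 = A0, H1 = H1,
                                       H2 = H2, S1 = S1, S2 = S2)
    R <- R - Bc
  }
  list(forecast = Ftot, cache = cache, residual = R, block_forecasts = Fblocks)
}

# Reverse-mode gradients for one minibatch given dL/dforecast per channel.
nhits_backward_pass <- function(blocks, config, Z, fw, dF) {
  n_ch <- n_output_channels(config$loss)
  T0 <- config$lookback
  B <- nrow(Z)
  grads <- vector("list", length(blocks))
  dR <- matrix(0, B, T0)
  for (j in rev(seq_along(blocks))) {
    blk <- blocks[[j]]
    cc <- fw$cache[[j]]
    dBc <- -dR
    g <- list(Wb = crossprod(cc$H2, dBc), bb = colSums(dBc),
              Wf = vector("list", n_ch), bf = vector("list", n_ch))
    dH2 <- dBc %*% t(blk$Wb)
    for (c in seq_len(n_ch)) {
      dK <- dF[[c]] %*% blk$M
      g$Wf[[c]] <- crossprod(cc$H2, dK)
      g$bf[[c]] <- colSums(dK)
      dH2 <- dH2 + dK %*% t(blk$Wf[[c]])
    }
    dS2 <- dH2 * (cc$S2 > 0)
    g$W2 <- crossprod(cc$H1, dS2); g$b2 <- colSums(dS2)
    dH1 <- dS2 %*% t(blk$W2)
    dS1 <- dH1 * (cc$S1 > 0)
    g$W1 <- crossprod(cc$A0, dS1); g$b1 <- colSums(dS1)
    dA0 <- dS1 %*% t(blk$W1)
    dP <- dA0[, seq_len(blk$Lp), drop = FALSE]
    # route pooled gradients back to the argmax cells, plus the residual
    # pass-through to earlier blocks
    for (gg in seq_len(blk$Lp)) {
      cols <- blk$groups[[gg]]
      tgt <- if (length(cols) == 1L) rep(cols, B) else cols[cc$amax[, gg]]
      idx <- cbind(seq_len(B), tgt)
      dR[idx] <- dR[idx] + dP[, gg]
    }
    grads[[j]] <- g
  }
  grads
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Loss value and gradient w.r.t. the per-channel forecast sums.
nhits_loss <- function(Ftot, C, config, with_grad = FALSE) {
  B <- nrow(C); H <- ncol(C); n <- B * H
  if (config$loss == "mae") {
    E <- Ftot[[1L]] - C
    val <- mean(abs(E))
    if (!with_grad) return(list(value = val))
    list(value = val, dF = list(sign(E) / n))
  } else if (config$loss == "gaussian") {
    mu <- Ftot[[1L]]; p <- Ftot[[2L]]
    sigma <- softplus(p) + 1e-6
    E <- mu - C
    val <- mean(0.5 * log(2 * pi * sigma^2) + E^2 / (2 * sigma^2))
    if (!with_grad) return(list(value = val))
    dmu <- E / sigma^2 / n
    dsig <- (1 / sigma - E^2 / sigma^3) / n
    dp <- dsig * stats::plogis(p)
    list(value = val, dF = list(dmu, dp))
  } else {
    qs <- quantile_levels(config$level)
    val <- 0
    dF <- vector("list", 3L)
    for (i in 1:3) {
      E <- C - Ftot[[i]]
      val <- val + mean(qs[i] * pmax(E, 0) + (1 - qs[i]) * pmax(-E, 0)) / 3
      if (with_grad) dF[[i]] <- ((Ftot[[i]] > C) * (1 - qs[i]) -
                                   (Ftot[[i]] < C) * qs[i]) / (n * 3)
    }
    if (!with_grad) return(list(value = val))
    list(value = val, dF = dF)
  }
}

quantile_levels <- function(level) c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)

# Adam update applied in place over the nested block parameter lists.
adam_step <- function(blocks, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p, m, v)
  }
  for (j in seq_along(blocks)) {
    for (nm in c("W1", "b1", "W2", "b2", "Wb", "bb")) {
      r <- upd(blocks[[j]][[nm]], grads[[j]][[nm]],
               state$m[[j]][[nm]], state$v[[j]][[nm]])
      blocks[[j]][[nm]] <- r[[1L]]; state$m[[j]][[nm]] <- r[[2L]]
      state$v[[j]][[nm]] <- r[[3L]]
    }
    for (c in seq_along(blocks[[j]]$Wf)) {
      for (nm in c("Wf", "bf")) {
        r <- upd(blocks[[j]][[nm]][[c]], grads[[j]][[nm]][[c]],
                 state$m[[j]][[nm]][[c]], state$v[[j]][[nm]][[c]])
        blocks[[j]][[nm]][[c]] <- r[[1L]]; state$m[[j]][[nm]][[c]] <- r[[2L]]
        state$v[[j]][[nm]][[c]] <- r[[3L]]
      }
    }
  }
  list(blocks = blocks, state = state)
}

zero_like_blocks <- function(blocks) {
  lapply(blocks, function(blk) {
    z <- lapply(blk[c("W1", "b1", "W2", "b2", "Wb", "bb")],
                function(p) p * 0)
    z$Wf <- lapply(blk$Wf, function(p) p * 0)
    z$bf <- lapply(blk$bf, function(p) p * 0)
    z
  })
}

#' Fit an N-HiTS forecaster
#'
#' Trains the stacked-block forecaster by Adam with minibatches and early
#' stopping: training halts when the validation loss has not improved for
#' `patience` epochs, and the best-validation parameters are restored.
#' Fully reproducible from the config seed.
#'
#' @param train_windows,val_windows `window_set` objects from
#'   [make_windows()] (scaled units). Lookback/horizon must match the
#'   config.
#' @param config An [nhits_config()].
#' @return An object of class `nhits_model` with the trained parameters and
#'   a per-epoch loss `history` tibble.
#' @export
fit_nhits <- function(train_windows, val_windows, config) {
  stopifnot(inherits(config, "nhits_config"))
  for (w in list(train_windows, val_windows)) {
    if (nrow(w$X) == 0L) stop("empty window set", call. = FALSE)
    if (w$lookback != config$lookback || w$horizon != config$horizon) {
      stop("window lookback/horizon do not match the model config", call. = FALSE)
    }
  }
  z_dim <- ncol(train_windows$Z)
  n_tr <- nrow(train_windows$X)
  local_seed(config$seed, {
    blocks <- init_nhits(config, z_dim)
    state <- list(m = zero_like_blocks(blocks), v = zero_like_blocks(blocks))
    best <- list(loss = Inf, blocks = blocks, epoch = 0L)
    wait <- 0L; t_step <- 0L
    hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        X <- train_windows$X[idx, , drop = FALSE]
        Z <- train_windows$Z[idx, , drop = FALSE]
        C <- train_windows$C[idx, , drop = FALSE]
        fw <- nhits_forward_pass(blocks, config, X, Z, keep_cache = TRUE)
        ls <- nhits_loss(fw$forecast, C, config, with_grad = TRUE)
        grads <- nhits_backward_pass(blocks, config, Z, fw, ls$dF)
        t_step <- t_step + 1L
        r <- adam_step(blocks, grads, state, config$learning_rate, t_step)
        blocks <- r$blocks; state <- r$state
        ep_loss <- ep_loss + ls$value; n_batches <- n_batches + 1L
      }
      vw <- nhits_forward_pass(blocks, config, val_windows$X, val_windows$Z)
      val_loss <- nhits_loss(vw$forecast, val_windows$C, config)$value
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, ep_loss / n_batches)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, blocks = blocks, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(config = config, blocks = best$blocks,
                   best_epoch = best$epoch, best_val_loss = best$loss,
                   z_dim = z_dim,
                   covariates = train_windows$covariates,
                   target = train_windows$target,
                   history = tibble::tibble(epoch = hist_epoch,
                                            train_loss = hist_train,
                                            val_loss = hist_val)),
              class = "nhits_model")
  })
}

#' @export
print.nhits_model <- function(x, ...) {
  cat(sprintf(paste0("N-HiTS model (%s loss): %d stack(s), %d block(s), ",
                     "lookback %d -> horizon %d\n"),
              x$config$loss, x$config$n_stacks, length(x$blocks),
              x$config$lookback, x$config$horizon))
  cat(sprintf("  best validation loss %.6g at epoch %d of %d run\n",
              x$best_val_loss, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Predict from a fitted N-HiTS model
#'
#' @param object A fitted `nhits_model`.
#' @param windows A `window_set` with matching lookback/horizon.
#' @param ... Unused.
#' @return For an `"mae"` model, a `windows x horizon` matrix of point
#'   forecasts. For a `"gaussian"` model, a list with matrices `mu` and
#'   `sigma` (class `gaussian_forecast_matrix`). For a `"quantile"` model, a
#'   list with matrices `lower`, `median`, `upper`.
#' @export
predict.nhits_model <- function(object, windows, ...) {
  if (windows$lookback != object$config$lookback ||
      windows$horizon != object$config$horizon) {
    stop("window lookback/horizon do not match the model", call. = FALSE)
  }
  fw <- nhits_forward_pass(object$blocks, object$config, windows$X, windows$Z)
  F <- fw$forecast
  if (object$config$loss == "mae") {
    F[[1L]]
  } else if (object$config$loss == "gaussian") {
    structure(list(mu = F[[1L]], sigma = softplus(F[[2L]]) + 1e-6),
              class = "gaussian_forecast_matrix")
  } else {
    lo <- pmin(F[[1L]], F[[2L]], F[[3L]])
    up <- pmax(F[[1L]], F[[2L]], F[[3L]])
    med <- pmin(pmax(F[[2L]], lo), up)
    list(lower = lo, median = med, upper = up, level = object$config$level)
  }
}
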