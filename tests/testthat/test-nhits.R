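test_that("multi-rate pooling follows the ceiling-padded max rule", {
  expect_equal(multirate_pool(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(multirate_pool(c(1, 5, 2, 4), 2), c(5, 4))
  expect_equal(multirate_pool(c(1, 5, 2), 2), c(5, 2))
  m <- rbind(c(1, 5, 2, 4), c(7, 0, 3, 3))
  expect_equal(multirate_pool(m, 2), rbind(c(5, 4), c(7, 3)))
  expect_equal(multirate_pool(m, 1), m)
  expect_error(multirate_pool(1:4, 0), ">= 1")
})

test_that("knot interpolation is identity at full rate and constant at one knot", {
  expect_equal(interp_matrix(6, 6), diag(6))
  expect_equal(interp_matrix(5, 1), matrix(1, 5, 1))
  # endpoints pinned: first/last forecast values equal first/last knots
  M <- interp_matrix(6, 3)
  knots <- c(2, -1, 4)
  f <- as.numeric(M %*% knots)
  expect_equal(f[1], 2)
  expect_equal(f[6], 4)
  # interior values linearly interpolate the knots
  expect_equal(f, approx(seq(1, 6, length.out = 3), knots, xout = 1:6)$y)
})

test_that("a model with all-zero parameters outputs zero backcast and forecast", {
  cfg <- nhits_config(lookback = 6, horizon = 3, n_stacks = 2, n_blocks = 1,
                      mlp_units = 5, n_pool_kernel_size = 2,
                      n_freq_downsample = c(2, 1), loss = "mae", seed = 1)
  blocks <- greenhits:::init_nhits(cfg, z_dim = 0)
  for (j in seq_along(blocks)) {
    for (nm in c("W1", "b1", "W2", "b2", "Wb", "bb")) {
      blocks[[j]][[nm]] <- blocks[[j]][[nm]] * 0
    }
  }
  X <- matrix(rnorm(12), 2, 6)
  fw <- greenhits:::nhits_forward_pass(blocks, cfg, X, matrix(0, 2, 0))
  expect_equal(fw$forecast[[1]], matrix(0, 2, 3))
  expect_equal(fw$residual, X)   # zero backcasts leave the input untouched
})

test_that("the model forecast is the sum of per-block forecasts", {
  set.seed(12)
  cfg <- nhits_config(lookback = 8, horizon = 4, n_stacks = 3, n_blocks = 2,
                      mlp_units = 9, loss = "gaussian",
                      n_pool_kernel_size = c(3, 2, 1),
                      n_freq_downsample = c(4, 2, 1), seed = 5)
  blocks <- greenhits:::init_nhits(cfg, z_dim = 3)
  for (j in seq_along(blocks)) for (c in 1:2) {
    blocks[[j]]$Wf[[c]] <- matrix(rnorm(length(blocks[[j]]$Wf[[c]]), 0, 0.4),
                                  nrow(blocks[[j]]$Wf[[c]]))
  }
  X <- matrix(rnorm(32), 4, 8); Z <- matrix(rnorm(12), 4, 3)
  fw <- greenhits:::nhits_forward_pass(blocks, cfg, X, Z, collect_blocks = TRUE)
  for (c in 1:2) {
    total <- Reduce(`+`, lapply(fw$block_forecasts, `[[`, c))
    expect_equal(total, fw$forecast[[c]], tolerance = 1e-12)
  }
})

test_that("doubling a block's forecast head doubles its contribution only", {
  set.seed(13)
  cfg <- nhits_config(lookback = 6, horizon = 3, n_stacks = 2, n_blocks = 1,
                      mlp_units = 6, n_pool_kernel_size = 2,
                      n_freq_downsample = 1, loss = "mae", seed = 2)
  blocks <- greenhits:::init_nhits(cfg, z_dim = 0)
  for (j in 1:2) {
    blocks[[j]]$Wf[[1]] <- matrix(rnorm(18, 0, 0.3), 6, 3)
    blocks[[j]]$bf[[1]] <- rnorm(3, 0, 0.3)
  }
  X <- matrix(rnorm(18), 3, 6); Z <- matrix(0, 3, 0)
  base <- greenhits:::nhits_forward_pass(blocks, cfg, X, Z, collect_blocks = TRUE)
  doubled <- blocks
  doubled[[2]]$Wf[[1]] <- 2 * doubled[[2]]$Wf[[1]]
  doubled[[2]]$bf[[1]] <- 2 * doubled[[2]]$bf[[1]]
  out <- greenhits:::nhits_forward_pass(doubled, cfg, X, Z, collect_blocks = TRUE)
  expect_equal(out$block_forecasts[[2]][[1]], 2 * base$block_forecasts[[2]][[1]],
               tolerance = 1e-12)
  expect_equal(out$block_forecasts[[1]][[1]], base$block_forecasts[[1]][[1]])
})

test_that("one stack, one block, kernel 1, downsample 1 reduces to a plain MLP", {
  set.seed(14)
  cfg <- nhits_config(lookback = 7, horizon = 3, n_stacks = 1, n_blocks = 1,
                      mlp_units = 11, n_pool_kernel_size = 1,
                      n_freq_downsample = 1, loss = "mae", seed = 6)
  blocks <- greenhits:::init_nhits(cfg, z_dim = 4)
  blocks[[1]]$Wf[[1]] <- matrix(rnorm(33, 0, 0.3), 11, 3)
  blocks[[1]]$bf[[1]] <- rnorm(3, 0, 0.3)
  X <- matrix(rnorm(35), 5, 7); Z <- matrix(rnorm(20), 5, 4)
  fw <- greenhits:::nhits_forward_pass(blocks, cfg, X, Z)
  # independent plain-MLP evaluation from the same weights
  relu <- function(m) pmax(m, 0)
  b <- blocks[[1]]
  A0 <- cbind(X, Z)
  H2 <- relu(sweep(relu(sweep(A0 %*% b$W1, 2, b$b1, `+`)) %*% b$W2, 2, b$b2, `+`))
  mlp <- sweep(H2 %*% b$Wf[[1]], 2, b$bf[[1]], `+`)
  expect_equal(fw$forecast[[1]], mlp, tolerance = 1e-12)
})

test_that("a two-block forward pass matches an independent step-by-step trace", {
  # 4-point window, hand-sized weights; the oracle re-implements
  # pool -> MLP -> interpolate -> residual -> sum with explicit loops
  cfg <- nhits_config(lookback = 4, horizon = 2, n_stacks = 2, n_blocks = 1,
                      mlp_units = 2, n_pool_kernel_size = c(2, 1),
                      n_freq_downsample = c(2, 1), loss = "mae", seed = 1)
  blocks <- greenhits:::init_nhits(cfg, z_dim = 0)
  blocks[[1]][c("W1", "b1", "W2", "b2", "Wb", "bb")] <- list(
    matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2), c(0.1, 0),
    matrix(c(0.2, 0.4, -0.3, 0.1), 2, 2), c(0, 0.2),
    matrix(c(0.3, 0.1, -0.1, 0.2, 0.05, -0.2, 0.15, 0.25), 2, 4), rep(0.05, 4))
  blocks[[1]]$Wf[[1]] <- matrix(c(0.6, -0.4), 2, 1)
  blocks[[1]]$bf[[1]] <- 0.1
  blocks[[2]][c("W1", "b1", "W2", "b2", "Wb", "bb")] <- list(
    matrix(c(0.2, 0.1, -0.3, 0.4, 0.25, -0.15, 0.05, 0.35), 4, 2), c(0, 0.1),
    matrix(c(0.3, -0.2, 0.1, 0.2), 2, 2), c(0.1, 0),
    matrix(c(0.1, 0.2, 0.3, -0.1, 0.2, 0.1, -0.2, 0.3), 2, 4), rep(0, 4))
  blocks[[2]]$Wf[[1]] <- matrix(c(0.5, 0.2, -0.3, 0.4), 2, 2)
  blocks[[2]]$bf[[1]] <- c(0.05, -0.05)
  x <- c(1, 0.5, -0.25, 0.75)

  relu_v <- function(v) ifelse(v > 0, v, 0)
  # block 1: kernel 2 pooling on 4 points -> 2 values
  p1 <- c(max(x[1:2]), max(x[3:4]))
  h1 <- relu_v(as.numeric(p1 %*% blocks[[1]]$W1) + blocks[[1]]$b1)
  h2 <- relu_v(as.numeric(h1 %*% blocks[[1]]$W2) + blocks[[1]]$b2)
  back1 <- as.numeric(h2 %*% blocks[[1]]$Wb) + blocks[[1]]$bb
  knot1 <- as.numeric(h2 %*% blocks[[1]]$Wf[[1]]) + blocks[[1]]$bf[[1]]
  f1 <- rep(knot1, 2)                     # one knot spread over the horizon
  r <- x - back1
  # block 2: kernel 1 (identity pooling)
  g1 <- relu_v(as.numeric(r %*% blocks[[2]]$W1) + blocks[[2]]$b1)
  g2 <- relu_v(as.numeric(g1 %*% blocks[[2]]$W2) + blocks[[2]]$b2)
  knot2 <- as.numeric(g2 %*% blocks[[2]]$Wf[[1]]) + blocks[[2]]$bf[[1]]
  f2 <- knot2                             # two knots over horizon 2: identity
  expected <- f1 + f2

  fw <- greenhits:::nhits_forward_pass(blocks, cfg, matrix(x, 1), matrix(0, 1, 0))
  expect_equal(as.numeric(fw$forecast[[1]]), expected, tolerance = 1e-12)
})

test_that("training fits a constant target quickly and is seed-deterministic", {
  s <- tiny_series(y = rep(0.5, 60) + rep(c(0, 1e-9), 30))
  w <- make_windows(s, "y", character(), lookback = 4, horizon = 2)
  tr <- greenhits:::windows_subset(w, 1:40)
  va <- greenhits:::windows_subset(w, 41:55)
  cfg <- nhits_config(lookback = 4, horizon = 2, n_stacks = 1, n_blocks = 1,
                      mlp_units = 8, n_pool_kernel_size = 1,
                      n_freq_downsample = 1, loss = "mae",
                      learning_rate = 1e-2, max_epochs = 150, patience = 150,
                      seed = 3)
  fit <- fit_nhits(tr, va, cfg)
  expect_lt(tail(fit$history$train_loss, 1), 0.01)
  fit2 <- fit_nhits(tr, va, cfg)
  expect_identical(fit$history, fit2$history)

  expect_error(fit_nhits(greenhits:::windows_subset(w, integer(0)), va, cfg),
               "empty")
})

test_that("early stopping halts after exactly `patience` stale epochs", {
  s <- tiny_series(y = sin(1:80 / 5))
  w <- make_windows(s, "y", character(), lookback = 4, horizon = 1)
  tr <- greenhits:::windows_subset(w, 1:50)
  va <- greenhits:::windows_subset(w, 51:70)
  # zero learning rate: the first epoch sets the best, then nothing improves
  cfg <- nhits_config(lookback = 4, horizon = 1, n_stacks = 1, n_blocks = 1,
                      mlp_units = 4, n_pool_kernel_size = 1,
                      n_freq_downsample = 1, loss = "mae",
                      learning_rate = 1e-30, max_epochs = 200, patience = 7,
                      seed = 2)
  fit <- fit_nhits(tr, va, cfg)
  expect_equal(nrow(fit$history), 8L)   # 1 improving epoch + 7 stale
  expect_equal(fit$best_epoch, 1L)
})

test_that("model accessors summarize architecture and history", {
  sw <- sim_windows(n_days = 7, lookback = 6, horizon = 2)
  cfg <- nhits_config(lookback = 6, horizon = 2, mlp_units = 16,
                      loss = "gaussian", max_epochs = 3, patience = 50, seed = 1)
  fit <- fit_nhits(sw$train, sw$val, cfg)
  g <- generics::glance(fit)
  expect_equal(g$loss, "gaussian")
  expect_equal(g$epochs_run, 3L)
  expect_equal(nrow(generics::tidy(fit)), 3L)
  pred <- predict(fit, sw$test)
  expect_true(all(pred$sigma > 0))
  expect_equal(dim(pred$mu), dim(sw$test$C))
})
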