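test_that("the Gaussian heads are affine in the mean and softplus-positive in the scale", {
  set.seed(1)
  u <- 5
  w_mu <- matrix(rnorm(u * 3), u, 3); b_mu <- rnorm(3)
  w_s <- matrix(rnorm(u * 3), u, 3); b_s <- rnorm(3)
  ht <- matrix(rnorm(2 * u), 2, u)

  # zero pre-activation: sigma = ln 2 (+ floor)
  out0 <- gaussian_heads(matrix(0, 1, u), w_mu, b_mu, w_s * 0, rep(0, 3))
  expect_equal(as.numeric(out0$sigma), rep(log(2) + 1e-6, 3))

  # strongly negative pre-activation: sigma at the floor, never zero
  outneg <- gaussian_heads(matrix(0, 1, u), w_mu, b_mu, w_s * 0, rep(-500, 3))
  expect_true(all(outneg$sigma > 0))
  expect_equal(as.numeric(outneg$sigma), rep(1e-6, 3), tolerance = 1e-9)

  # mu is affine: heads(2*ht) - heads(ht) = ht %*% w_mu
  o1 <- gaussian_heads(ht, w_mu, b_mu, w_s, b_s)
  o2 <- gaussian_heads(2 * ht, w_mu, b_mu, w_s, b_s)
  expect_equal(o2$mu - o1$mu, ht %*% w_mu, tolerance = 1e-12)

  expect_error(gaussian_heads(matrix(NaN, 1, u), w_mu, b_mu, w_s, b_s),
               "non-finite")
})

test_that("the Gaussian NLL matches its closed form and the density oracle", {
  expect_equal(gaussian_nll(1, 1, 1), 0.5 * log(2 * pi))
  expect_equal(gaussian_nll(1, 1, 1), 0.9189385, tolerance = 1e-6)

  # for fixed sigma, the loss is minimized in mu at mu = c
  c0 <- 0.7
  nlls <- vapply(seq(-1, 2, by = 0.1),
                 function(m) gaussian_nll(c0, m, 0.5), 0)
  expect_equal(seq(-1, 2, by = 0.1)[which.min(nlls)], 0.7)

  # brute-force -log density agreement at random parameter draws
  set.seed(4)
  for (i in 1:100) {
    cc <- rnorm(1); mu <- rnorm(1); sig <- runif(1, 0.05, 3)
    expect_equal(gaussian_nll(cc, mu, sig), -log(dnorm(cc, mu, sig)),
                 tolerance = 1e-10)
  }
  expect_error(gaussian_nll(1, 1, 0), "positive")
})

test_that("Monte-Carlo intervals recover the Gaussian quantiles", {
  mu <- matrix(c(0, 2, -1, 0.5), 2, 2)
  sigma <- matrix(c(1, 0.5, 2, 0.1), 2, 2)
  iv <- mc_intervals(mu, sigma, n_samples = 10000, level = 0.90, seed = 42)
  z <- qnorm(0.95)
  expect_true(all(abs(iv$lower - (mu - z * sigma)) < 0.05 * sigma))
  expect_true(all(abs(iv$upper - (mu + z * sigma)) < 0.05 * sigma))
  expect_true(all(abs(iv$median - mu) < 0.05 * sigma))
  expect_true(all(iv$lower <= iv$median & iv$median <= iv$upper))

  # degenerate scale collapses the interval onto mu
  iv0 <- mc_intervals(mu, sigma * 0, n_samples = 100, seed = 1)
  expect_equal(iv0$lower, mu)
  expect_equal(iv0$median, mu)
  expect_equal(iv0$upper, mu)

  # seeded reproducibility
  expect_identical(mc_intervals(mu, sigma, 500, seed = 7),
                   mc_intervals(mu, sigma, 500, seed = 7))
})

test_that("scaling sigma by k scales the interval width by about k", {
  mu <- matrix(0, 1, 1); sigma <- matrix(1, 1, 1)
  iv1 <- mc_intervals(mu, sigma, n_samples = 20000, seed = 3)
  iv3 <- mc_intervals(mu, 3 * sigma, n_samples = 20000, seed = 3)
  ratio <- (iv3$upper - iv3$lower) / (iv1$upper - iv1$lower)
  expect_equal(as.numeric(ratio), 3, tolerance = 0.05)
})

test_that("residual-based calibrators honour symmetry and degenerate residuals", {
  # all-zero residuals: degenerate interval at the point forecast
  cal0 <- interval_from_errors(matrix(0, 20, 2), method = "error_fit")
  iv0 <- apply_calibrator(cal0, matrix(1:6 / 2, 3, 2))
  expect_equal(iv0$lower, iv0$median)
  expect_equal(iv0$upper, iv0$median)

  # symmetric residual pool gives a symmetric interval around the forecast
  set.seed(9)
  r <- rnorm(500)
  res <- cbind(c(r, -r))
  for (m in c("error_fit", "bootstrap")) {
    cal <- interval_from_errors(res, method = m, seed = 5)
    expect_equal(cal$lower, -cal$upper, tolerance = 0.12)
  }

  expect_error(interval_from_errors(matrix(0, 5, 2)), "at least 10")
})

test_that("a well-specified residual calibrator covers near the nominal level", {
  set.seed(11)
  n_val <- 400; n_test <- 2000
  for (m in c("error_fit", "bootstrap")) {
    res_val <- matrix(rnorm(n_val), ncol = 1)
    cal <- interval_from_errors(res_val, method = m, level = 0.90, seed = 2)
    point <- matrix(rnorm(n_test, 5, 2), ncol = 1)
    obs <- point + rnorm(n_test)
    iv <- apply_calibrator(cal, point)
    picp <- mean(obs >= iv$lower & obs <= iv$upper)
    expect_gte(picp, 0.83)
    expect_lte(picp, 0.97)
  }
})

test_that("pinball loss is zero at the target, halves absolute error at the median, and is asymmetric", {
  expect_equal(pinball_loss(c(1, 2), c(1, 2), 0.3), 0)
  set.seed(12)
  a <- rnorm(50); p <- rnorm(50)
  expect_equal(pinball_loss(a, p, 0.5), mean(abs(a - p)) / 2, tolerance = 1e-12)
  q <- 0.9
  under <- pinball_loss(1, 0, q)   # prediction below the actual
  over <- pinball_loss(0, 1, q)    # prediction above by the same amount
  expect_equal(under / over, q / (1 - q), tolerance = 1e-12)
})

test_that("quantile-loss training yields ordered intervals", {
  sw <- sim_windows(n_days = 7, lookback = 6, horizon = 2)
  cfg <- nhits_config(lookback = 6, horizon = 2, mlp_units = 16,
                      loss = "quantile", max_epochs = 15, patience = 50,
                      seed = 4)
  fit <- fit_nhits(sw$train, sw$val, cfg)
  iv <- predict(fit, sw$test)
  expect_true(all(iv$lower <= iv$median & iv$median <= iv$upper))
})
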