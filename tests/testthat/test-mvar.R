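test_that("coefficients of the bivariate system are recovered at large n", {
  net <- bivariate_net(0.5)
  rec <- simulate_mvar(net, 50000, seed = 21)
  fit <- mvar(rec, order = 1)
  A <- coef(fit)[, , 1]
  expect_equal(A[2, 1], 0.5, tolerance = 0.04)
  expect_lt(max(abs(A[cbind(c(1, 1, 2), c(1, 2, 2))])), 0.02)
})

test_that("a noise-free recursion is inverted to machine precision", {
  A <- matrix(c(0.6, 0.4, -0.3, 0.5), 2, 2)
  net <- mvar_network(A, noise_sd = 1)
  # drive a short deterministic recursion from a nonzero state; the mirrored
  # second epoch makes the channel means exactly zero, so demeaning does not
  # disturb the exact recursion (short, to keep the decay well-conditioned)
  net$noise_sd <- c(0, 0)
  rec <- simulate_mvar(net, 60, burn_in = 0, seed = 1,
                       init = matrix(c(3, -2), 1, 2))
  both <- eeg_recording(cbind(rec$data, -rec$data), fs = rec$fs,
                        labels = rec$labels)
  both <- epoch_recording(both, 60 / both$fs)
  fit <- mvar(both, order = 1)
  expect_lt(max(abs(coef(fit)[, , 1] - A)), 1e-8)
})

test_that("white-noise residual covariance is approximately identity", {
  rec <- white_noise_rec(4, 20000, seed = 22)
  fit <- mvar(rec, order = 1)
  expect_equal(unname(fit$noise_cov), diag(4), tolerance = 0.05)
})

test_that("SBC recovers the generating order and penalises white noise", {
  rec3 <- simulate_mvar(order3_net(), 20000, seed = 23)
  sel <- select_order(rec3, 1, 8)
  expect_equal(sel$order, 3L)
  expect_equal(nrow(sel$criteria), 8L)

  recw <- white_noise_rec(4, 5000, seed = 24)
  expect_equal(select_order(recw, 1, 6)$order, 1L)

  rec1 <- simulate_mvar(bivariate_net(), 20000, seed = 25)
  expect_equal(select_order(rec1, 1, 6)$order, 1L)
})

test_that("coefficient error shrinks with sample size (consistency)", {
  net <- bivariate_net(0.5)
  rmse <- sapply(c(4000, 40000), function(n) {
    rec <- simulate_mvar(net, n, seed = 26)
    sqrt(mean((coef(mvar(rec, order = 1)) - net$coupling)^2))
  })
  expect_lt(rmse[2], rmse[1])
})

test_that("pooled multi-epoch fitting equals single-epoch fitting on one epoch", {
  rec <- simulate_mvar(order3_net(), 3000, seed = 27, fs = 100)
  plain <- mvar(rec, order = 3)
  one_epoch <- mvar(epoch_recording(rec, 30), order = 3)
  expect_equal(coef(plain), coef(one_epoch))
  expect_equal(plain$noise_cov, one_epoch$noise_cov)
})

test_that("epoched fitting uses only within-epoch lag windows", {
  rec <- simulate_mvar(order3_net(), 3000, seed = 28, fs = 100)
  epoched <- epoch_recording(rec, 5)   # 6 epochs of 500
  fit <- mvar(epoched, order = 3)
  # 3 lag-invalid rows lost per epoch
  expect_equal(fit$n_samples_used, 3000 - 6 * 3)
  expect_equal(unname(coef(fit)[2, 3, 2]), 0.4, tolerance = 0.05)
})

test_that("order selection validates its inputs", {
  rec <- white_noise_rec(3, 500, seed = 29)
  expect_error(select_order(rec, 5, 2), "exceeds")
  expect_error(select_order(rec, 1, 30), "identifiability")
})

test_that("a duplicated channel raises a conditioning error naming it", {
  set.seed(30)
  x <- rnorm(2000)
  rec <- eeg_recording(rbind(x, x, rnorm(2000)), fs = 100,
                       labels = c("F3", "F4", "Cz"))
  expect_error(mvar(rec, order = 1), "rank-deficient.*F3|F4")
})

test_that("mvar methods behave like a standard model object", {
  net <- bivariate_net()
  rec <- simulate_mvar(net, 5000, seed = 31)
  fit <- mvar(rec)     # auto order selection
  expect_equal(fit$order, 1L)
  expect_s3_class(fit, "mvar")
  expect_output(print(fit), "order 1")
  s <- summary(fit)
  expect_lt(s$radius, 1)
  expect_true(is_stable(fit))
  expect_equal(dim(residuals(fit)), c(fit$n_samples_used, 2L))
  # residuals should be serially uncorrelated
  e <- residuals(fit)
  expect_lt(abs(stats::cor(e[-1, 1], e[-nrow(e), 1])), 0.05)
  # one-step predictions reduce variance below the raw signal variance
  pred <- predict(fit, rec)
  err <- rec$data[2, -1] - pred[2, -1]
  expect_lt(stats::var(err, na.rm = TRUE), stats::var(rec$data[2, ]))
  # simulate() round-trips through a network with the fitted coefficients
  sim <- simulate(fit, nsim = 500, seed = 1)
  expect_s3_class(sim, "eeg_recording")
  expect_equal(ncol(sim$data), 500L)
})

test_that("MVAR models serialize to JSON and back losslessly", {
  rec <- simulate_mvar(order3_net(), 5000, seed = 32)
  fit <- mvar(rec, order = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_mvar_json(fit, path)
  back <- read_mvar_json(path)
  expect_equal(back$coef, fit$coef)
  expect_equal(back$noise_cov, fit$noise_cov)
  expect_equal(back$order, fit$order)
  expect_equal(back$sbc, unname(fit$sbc))
})
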