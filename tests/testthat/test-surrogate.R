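test_that("surrogate test keeps the true link and prunes the reverse one", {
  rec <- simulate_mvar(bivariate_net(0.5), 20000, seed = 51, fs = 128)
  d <- dtf(mvar(rec, order = 1))
  null <- surrogate_null(rec, order = 1, n_shuffles = 200, seed = 52)
  pr <- prune(d, null, alpha = 0.05)
  expect_true(pr$keep[2, 1])
  expect_false(pr$keep[1, 2])
  expect_lt(pr$p_values[2, 1], 0.01)
  expect_gt(pr$p_values[1, 2], 0.05)
  # pruned matrix zeroes the removed link and recomputes the scalar summary
  expect_equal(pr$dtf$band_mean[1, 2], 0)
  expect_equal(pr$dtf$dtf_mean, mean(c(pr$dtf$band_mean[2, 1], 0)))
})

test_that("surrogate p-values are deterministic given the seed", {
  rec <- simulate_mvar(bivariate_net(0.3), 2000, seed = 53, fs = 128)
  d <- dtf(mvar(rec, order = 1))
  n1 <- surrogate_null(rec, order = 1, n_shuffles = 150, seed = 99)
  n2 <- surrogate_null(rec, order = 1, n_shuffles = 150, seed = 99)
  expect_identical(n1$null_values, n2$null_values)
  expect_identical(prune(d, n1)$p_values, prune(d, n2)$p_values)
})

test_that("add-one p-values are bounded away from zero and behave at extremes", {
  # synthetic null object around a hand-built observed dtf
  nv <- array(NA_real_, c(2, 2, 200))
  set.seed(54)
  nv[2, 1, ] <- runif(200, 0, 0.1)
  nv[1, 2, ] <- runif(200, 0, 0.1)
  null <- structure(list(null_values = nv, n_shuffles = 200, alpha = 0.05,
                         seed = 54, order = 1, freqs = seq(1, 45, 0.5),
                         band = c(30, 45), labels = c("a", "b"),
                         n_retries = 0L),
                    class = "surrogate_null")
  obs <- dtf(matrix(c(0, 0.5, 0, 0), 2, 2), fs = 128)  # gamma21 = 0.2 >> null
  pr <- prune(obs, null, alpha = 0.05)
  expect_equal(pr$p_values[2, 1], 1 / 201)
  expect_true(pr$keep[2, 1])
  expect_gt(min(pr$p_values, na.rm = TRUE), 0)
  # observed at the null median -> removed with p about 0.5
  nv2 <- nv
  nv2[2, 1, ] <- seq(0.1, 0.3, length.out = 200)   # median 0.2 = observed
  null2 <- null; null2$null_values <- nv2
  pr2 <- prune(obs, null2, alpha = 0.05)
  expect_false(pr2$keep[2, 1])
  expect_equal(pr2$p_values[2, 1], 0.5, tolerance = 0.02)
  # everything below the null 95th percentile -> empty off-diagonal
  nv3 <- nv
  nv3[2, 1, ] <- runif(200, 0.5, 1)
  null3 <- null; null3$null_values <- nv3
  pr3 <- prune(obs, null3, alpha = 0.05)
  expect_equal(sum(pr3$dtf$band_mean[row(diag(2)) != col(diag(2))]), 0)
})

test_that("pruning refuses a null built under a different configuration", {
  rec <- simulate_mvar(bivariate_net(0.3), 2000, seed = 55, fs = 128)
  d30 <- dtf(mvar(rec, order = 1), band = c(30, 45))
  null20 <- surrogate_null(rec, order = 1, band = c(20, 30), n_shuffles = 100,
                           seed = 1)
  expect_error(prune(d30, null20), "configuration mismatch")
  null_o2 <- surrogate_null(rec, order = 2, n_shuffles = 100, seed = 1)
  expect_error(prune(d30, null_o2), "order")
})

test_that("few shuffles triggers a quantile-resolution warning", {
  rec <- white_noise_rec(2, 500, seed = 56)
  expect_warning(surrogate_null(rec, order = 1, n_shuffles = 50, seed = 1),
                 "coarse null quantiles")
})

test_that("false-positive rate on white noise is near the nominal level", {
  # 25 independent null datasets x 56 links: enough to bound the rate coarsely;
  # the full calibration lives in the acceptance suite
  hits <- 0; links <- 0
  for (s in 1:25) {
    rec <- white_noise_rec(8, 800, fs = 128, seed = 600 + s)
    d <- dtf(mvar(rec, order = 1))
    null <- surrogate_null(rec, order = 1, n_shuffles = 100, seed = 700 + s)
    pr <- prune(d, null, alpha = 0.05)
    hits <- hits + sum(pr$keep, na.rm = TRUE)
    links <- links + sum(!is.na(pr$keep))
  }
  rate <- hits / links
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("detection power is non-decreasing in coupling strength", {
  power <- sapply(c(0.1, 0.3, 0.5), function(cpl) {
    det <- 0
    for (s in 1:5) {
      rec <- simulate_mvar(bivariate_net(cpl), 4000, seed = 800 + s, fs = 128)
      d <- dtf(mvar(rec, order = 1))
      null <- surrogate_null(rec, order = 1, n_shuffles = 100,
                             seed = 900 + s)
      det <- det + prune(d, null, alpha = 0.05)$keep[2, 1]
    }
    det / 5
  })
  expect_true(all(diff(power) >= 0))
  expect_equal(power[3], 1)
})

test_that("surrogate results serialize with seed and configuration", {
  rec <- simulate_mvar(bivariate_net(0.5), 4000, seed = 57, fs = 128)
  d <- dtf(mvar(rec, order = 1))
  null <- surrogate_null(rec, order = 1, n_shuffles = 100, seed = 58)
  pr <- prune(d, null)
  dir <- withr::local_tempdir()
  write_surrogate_results(pr, null, dir)
  expect_true(file.exists(file.path(dir, "links.csv")))
  js <- jsonlite::read_json(file.path(dir, "surrogate_summary.json"))
  expect_equal(js$seed, 58)
  expect_equal(js$n_shuffles, 100)
})
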