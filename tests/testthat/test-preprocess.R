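test_that("notch removes a 50 Hz tone almost completely", {
  fs <- 512
  tt <- seq_len(fs * 30) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 50 * tt)), fs = fs, labels = "c1")
  out <- condition(rec, lowpass_hz = NULL, notch_band = c(49, 51),
                   baseline_poly_order = NULL)
  rms_in <- sqrt(mean(rec$data^2))
  rms_out <- sqrt(mean(out$data^2))
  expect_lt(rms_out / rms_in, 0.03)
  # spectral attenuation at the notch centre (steady state) is far deeper
  p_in <- Mod(stats::fft(rec$data[1, ]))^2
  p_out <- Mod(stats::fft(out$data[1, ]))^2
  bin50 <- which.max(p_in)
  expect_lt(10 * log10(p_out[bin50] / p_in[bin50]), -30)
})

test_that("a linear ramp vanishes under order-1 baseline correction", {
  rec <- eeg_recording(rbind(seq(-3, 7, length.out = 1000)), fs = 100,
                       labels = "c1")
  out <- condition(rec, lowpass_hz = NULL, notch_band = NULL,
                   baseline_poly_order = 1)
  expect_lt(max(abs(out$data)), 1e-8)
})

test_that("low-pass attenuates white noise above the cutoff by >= 20 dB", {
  fs <- 512
  set.seed(4)
  rec <- eeg_recording(rbind(rnorm(fs * 20)), fs = fs, labels = "c1")
  out <- condition(rec, lowpass_hz = 100, notch_band = NULL,
                   baseline_poly_order = NULL)
  band_power <- function(x, f1, f2) {
    p <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    mean(p[fr >= f1 & fr <= f2])
  }
  atten <- 10 * log10(band_power(out$data[1, ], 110, 250) /
                      band_power(rec$data[1, ], 110, 250))
  expect_lt(atten, -20)
})

test_that("conditioning is nearly idempotent in the passband", {
  fs <- 256
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(2 * fs * 20), 2), fs = fs)
  once <- condition(rec, 100, c(49, 51), 3)
  twice <- condition(once, 100, c(49, 51), 3)
  band_power <- function(x, f1, f2) {
    p <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(p[fr >= f1 & fr <= f2])
  }
  for (i in 1:2) {
    p1 <- band_power(once$data[i, ], 1, 45)
    p2 <- band_power(twice$data[i, ], 1, 45)
    expect_lt(abs(p2 - p1) / p1, 0.01)
  }
})

test_that("conditioning rejects bands incompatible with the sampling rate", {
  rec <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 80)
  expect_error(condition(rec, lowpass_hz = 100), "Nyquist")
  expect_error(condition(rec, lowpass_hz = NULL, notch_band = c(49, 51)),
               "notch band")
})

test_that("artifact rejection drops exactly the epochs that exceed the limit", {
  fs <- 100
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(2 * fs * 10), 2), fs = fs)
  rec <- epoch_recording(rec, 1)
  # spike epochs 3 and 8 on different channels
  rec$data[1, 250] <- 1000
  rec$data[2, 790] <- -1000
  out <- reject_artifacts(rec, amplitude_limit = 100)
  log <- attr(out, "rejection_log")
  expect_equal(log$dropped, c(3L, 8L))
  expect_equal(out$n_epochs, 8L)
  expect_equal(ncol(out$data), 8L * fs)

  clean <- epoch_recording(eeg_recording(matrix(rnorm(2 * fs * 5), 2), fs = fs), 1)
  kept <- reject_artifacts(clean, amplitude_limit = 100)
  expect_equal(kept$data, clean$data)
  expect_equal(attr(kept, "rejection_log")$n_dropped, 0L)

  allbad <- clean
  allbad$data[1, ] <- 500
  expect_error(reject_artifacts(allbad, 100), "no data left")
})

test_that("SNR is the variance ratio against the designated noise interval", {
  fs <- 100
  # channel with sd 3 overall, first second sd 1
  set.seed(7)
  noise <- rnorm(fs, sd = 1)
  signal <- rnorm(9 * fs, sd = 3)
  x <- c(noise, signal)
  rec <- eeg_recording(rbind(x), fs = fs, labels = "c1")
  rep <- compute_snr(rec, noise_interval = c(0, 1))
  expect_equal(unname(rep$per_channel_snr),
               (stats::sd(x) / stats::sd(noise))^2)
  # signal identical to the noise interval -> SNR exactly 1
  flat <- eeg_recording(rbind(rep(noise, 10)), fs = fs, labels = "c1")
  rep2 <- compute_snr(flat, noise_interval = c(0, 10))
  expect_equal(unname(rep2$per_channel_snr), 1)
})

test_that("SNR on generated data with known component sds is close to theory", {
  fs <- 200
  set.seed(8)
  noise_part <- rnorm(fs, sd = 0.9)
  sig_part <- rnorm(fs * 60, sd = 2.5)
  rec <- eeg_recording(rbind(c(noise_part, sig_part)), fs = fs, labels = "c1")
  rep <- compute_snr(rec, noise_interval = c(0, 1))
  # the noise-interval variance is estimated from fs samples, so the SNR
  # estimate carries ~10% Monte-Carlo error of its own
  expect_equal(unname(rep$per_channel_snr), (2.5 / 0.9)^2, tolerance = 0.2)
})

test_that("SNR guards against degenerate inputs", {
  rec <- eeg_recording(rbind(c(rep(1, 100), rnorm(100))), fs = 100,
                       labels = "c1")
  expect_error(compute_snr(rec, noise_interval = c(0, 1)), "zero-variance")
  expect_error(compute_snr(rec, noise_interval = c(0, 100)), "inside the recording")
})

test_that("the SNR gate reports channels inside the working range", {
  rep <- structure(list(per_channel_snr = c(a = 8, b = 9.5, c = 3, d = 20)),
                   class = "snr_report")
  g <- snr_gate(rep, lower = 7, upper = 10)
  expect_equal(unname(g$pass), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(g$failed, c("c", "d"))
})
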