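# Shared fixtures: small ground-truth networks used across test files.

# Bivariate system with a single directed edge 1 -> 2 at lag 1.
# Closed-form DTF: gamma_21^2 = 0.2, gamma_12^2 = 0 at every frequency.
bivariate_net <- function(coupling = 0.5, noise_sd = 1) {
  A <- matrix(0, 2, 2)
  A[2, 1] <- coupling
  mvar_network(A, noise_sd = noise_sd, labels = c("ch1", "ch2"))
}

# Three-channel order-3 system with strong, identifiable coefficients.
order3_net <- function() {
  A <- array(0, c(3, 3, 3))
  A[, , 1] <- 0.3 * diag(3)
  A[1, 2, 1] <- 0.4
  A[2, 3, 2] <- 0.4
  A[3, 1, 3] <- 0.4
  A[1, 1, 3] <- -0.3
  mvar_network(A, labels = c("ch1", "ch2", "ch3"))
}

white_noise_rec <- function(n_channels, n_samples, fs = 128, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * n_samples), n_channels), fs = fs)
}

# Mean sample correlation among within- and between-community voxel pairs.
block_correlations <- function(vol) {
  Tn <- dim(vol$data)[4]
  ts <- t(matrix(vol$data, ncol = Tn)[which(vol$mask == 1), , drop = FALSE])
  C <- stats::cor(ts)
  lab <- vol$community_labels
  same <- outer(lab, lab, "==") & upper.tri(C)
  diff <- !outer(lab, lab, "==") & upper.tri(C)
  list(within = mean(C[same]),
       between = if (any(diff)) mean(C[diff]) else NA_real_)
}
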