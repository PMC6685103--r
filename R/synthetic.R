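#' Ground-truth MVAR coupling network
#'
#' Defines the generating process X(t) = sum_n A_n X(t-n) + E(t): a set of
#' lag coefficient matrices plus per-channel innovation standard deviations.
#' Stability (stationarity) is enforced at construction via the companion
#' matrix: all its eigenvalues must lie strictly inside the unit circle.
#'
#' @param coupling lag coefficients: an N x N matrix (order 1), an
#'   N x N x p array, or a list of p square matrices.  Entry `[i, j]` of lag
#'   matrix n is the influence of channel j at lag n on channel i.
#' @param noise_sd innovation standard deviation, scalar or length-N vector.
#' @param labels optional channel labels (defaults to the 10-20 montage).
#' @return An object of class `mvar_network` with elements `coupling`
#'   (N x N x p array), `noise_sd`, `n_channels`, `order`, `labels`,
#'   `edge_set` (data.frame of ordered source -> target pairs with nonzero
#'   off-diagonal coupling at any lag) and `spectral_radius`.
#' @export
#' @examples
#' net <- mvar_network(matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE))
#' net$edge_set
mvar_network <- function(coupling, noise_sd = 1, labels = NULL) {
  A <- as_coef_array(coupling)
  N <- dim(A)[1]; p <- dim(A)[3]
  noise_sd <- rep_len(as.numeric(noise_sd), N)
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive")
  rho <- companion_radius(A)
  if (rho >= 1)
    stop(sprintf(
      "unstable coefficient set: companion-matrix spectral radius %.4f >= 1",
      rho))
  if (is.null(labels)) labels <- montage_1020(N)
  nz <- apply(abs(A), c(1, 2), max) > 0
  diag(nz) <- FALSE
  idx <- which(nz, arr.ind = TRUE)
  edge_set <- data.frame(source = idx[, "col"], target = idx[, "row"])
  edge_set <- edge_set[order(edge_set$source, edge_set$target), , drop = FALSE]
  rownames(edge_set) <- NULL
  structure(list(coupling = A, noise_sd = noise_sd, n_channels = N,
                 order = p, labels = labels, edge_set = edge_set,
                 spectral_radius = rho),
            class = "mvar_network")
}

#' @export
print.mvar_network <- function(x, ...) {
  cat(sprintf("<mvar_network> %d channels, order %d, %d directed edges, spectral radius %.3f\n",
              x$n_channels, x$order, nrow(x$edge_set), x$spectral_radius))
  invisible(x)
}

as_coef_array <- function(coupling) {
  if (is.list(coupling)) coupling <- simplify2array(coupling)
  if (is.matrix(coupling)) coupling <- array(coupling, c(dim(coupling), 1L))
  if (!is.array(coupling) || length(dim(coupling)) != 3L ||
      dim(coupling)[1] != dim(coupling)[2])
    stop("`coupling` must be a square matrix, N x N x p array, or list of square matrices")
  storage.mode(coupling) <- "double"
  coupling
}

# Spectral radius of the Np x Np companion matrix of the lag polynomial.
companion_radius <- function(A) {
  N <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, N * p, N * p)
  for (n in seq_len(p)) C[seq_len(N), (n - 1L) * N + seq_len(N)] <- A[, , n]
  if (p > 1L)
    C[N + seq_len(N * (p - 1L)), seq_len(N * (p - 1L))] <- diag(N * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a multichannel recording from an MVAR network
#'
#' Runs the autoregressive recursion with Gaussian i.i.d. innovations and
#' discards an initial burn-in so the returned samples come from the
#' stationary regime.
#'
#' @param network an [mvar_network()].
#' @param n_samples number of samples to return.
#' @param fs sampling rate attached to the output (Hz); the process itself is
#'   defined in discrete time.
#' @param burn_in samples discarded before recording starts (default 1000).
#' @param seed integer seed; the output is bit-identical for equal seeds.
#' @param init optional p x N matrix of initial values (default zeros);
#'   mainly useful with `noise_sd` effectively zero to exercise the
#'   deterministic recursion.
#' @param labels optional channel labels passed to the recording.
#' @return An [eeg_recording()].
#' @export
simulate_mvar <- function(network, n_samples, fs = 512, burn_in = 1000,
                          seed = NULL, init = NULL, labels = NULL) {
  stopifnot(inherits(network, "mvar_network"))
  N <- network$n_channels; p <- network$order
  if (n_samples < 1L) stop("`n_samples` must be positive")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n_tot <- n_samples + burn_in
  E <- matrix(stats::rnorm(n_tot * N), nrow = N) * network$noise_sd
  X <- matrix(0, N, n_tot + p)
  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == p, ncol(init) == N)
    X[, seq_len(p)] <- t(init)
  }
  A <- network$coupling
  Astack <- matrix(aperm(A, c(1, 3, 2)), nrow = N)  # N x (p*N): lag-major cols
  for (t in seq_len(n_tot)) {
    xlag <- X[, (t + p - 1L):t, drop = FALSE]       # lags 1..p as columns
    X[, t + p] <- Astack %*% as.vector(t(xlag)) + E[, t]
  }
  out <- X[, p + burn_in + seq_len(n_samples), drop = FALSE]
  eeg_recording(out, fs = fs,
                labels = if (is.null(labels)) network$labels else labels)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Random stable sparse MVAR network
#'
#' Draws a sparse coupling structure and rescales it until the companion
#' spectral radius is below `radius`.  Used for property-style testing of the
#' spectral transform and DTF normalisation.
#'
#' @param n_channels,order network dimensions.
#' @param density probability of an off-diagonal directed edge.
#' @param strength coupling magnitude scale before stabilisation.
#' @param radius target upper bound on the spectral radius (default 0.9).
#' @param seed integer seed.
#' @return An [mvar_network()].
#' @export
random_stable_network <- function(n_channels, order = 1, density = 0.2,
                                  strength = 0.4, radius = 0.9, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  N <- n_channels
  A <- array(0, c(N, N, order))
  for (n in seq_len(order)) {
    M <- matrix(stats::rnorm(N * N, sd = strength), N, N) *
      matrix(stats::rbinom(N * N, 1L, density), N, N)
    diag(M) <- stats::runif(N, -0.3, 0.5) / order
    A[, , n] <- M
  }
  rho <- companion_radius(A)
  if (rho >= radius) A <- A * (radius / rho) * 0.98
  # rescaling a lag polynomial is not exactly linear in the radius; iterate
  while (companion_radius(A) >= radius) A <- A * 0.95
  mvar_network(A)
}

#' Attenuate the couplings of selected channels
#'
#' Scales every off-diagonal coupling into and out of the named channels by
#' `factor`, leaving self (diagonal) dynamics untouched.  This is how the
#' synthetic "patient" of the end-to-end study is built from a control-like
#' network: a lesion expressed as weakened directed interactions of the
#' posterior electrodes.
#'
#' @param network an [mvar_network()].
#' @param channels channel labels (or indices) to attenuate.
#' @param factor multiplicative factor in `[0, 1]`.
#' @return A new [mvar_network()].
#' @export
attenuate_couplings <- function(network, channels, factor = 0.2) {
  stopifnot(inherits(network, "mvar_network"), factor >= 0, factor <= 1)
  idx <- if (is.character(channels)) match(channels, network$labels)
         else as.integer(channels)
  if (anyNA(idx)) stop("unknown channels: ",
                       paste(channels[is.na(idx)], collapse = ", "))
  A <- network$coupling
  N <- dim(A)[1]
  for (n in seq_len(dim(A)[3])) {
    M <- A[, , n]
    d <- diag(M)
    M[idx, ] <- M[idx, , drop = FALSE] * factor
    M[, idx] <- M[, idx, drop = FALSE] * factor
    diag(M) <- d
    A[, , n] <- M
  }
  mvar_network(A, noise_sd = network$noise_sd, labels = network$labels)
}

#' Perturb coupling strengths multiplicatively
#'
#' Applies independent uniform jitter to every nonzero off-diagonal coupling;
#' models between-subject variability around a common network architecture.
#'
#' @param network an [mvar_network()].
#' @param jitter half-width of the uniform factor, e.g. 0.2 for U(0.8, 1.2).
#' @param seed integer seed.
#' @return A new [mvar_network()].
#' @export
jitter_network <- function(network, jitter = 0.2, seed = NULL) {
  stopifnot(inherits(network, "mvar_network"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  A <- network$coupling
  for (n in seq_len(dim(A)[3])) {
    M <- A[, , n]
    d <- diag(M)
    fac <- matrix(stats::runif(length(M), 1 - jitter, 1 + jitter), nrow(M))
    M <- M * fac
    diag(M) <- d
    A[, , n] <- M
  }
  mvar_network(A, noise_sd = network$noise_sd, labels = network$labels)
}

#' Block-correlated synthetic 4D volume
#'
#' Generates voxel time series inside a mask as community-shared latent
#' factors plus voxel noise, mixed so that the expected pairwise Pearson
#' correlation is `within_r` inside a community and `between_r` across
#' communities.  Cross-community correlation is induced by a single global
#' factor shared by all community factors.
#'
#' @param shape integer length-3 spatial extents.
#' @param n_timepoints number of volumes (time axis).
#' @param n_communities number of equally sized voxel communities.
#' @param within_r,between_r target correlations, `0 <= between_r < within_r < 1`
#'   (equality of both to 0 is allowed and yields independent noise).
#' @param seed integer seed.
#' @param mask optional logical/0-1 3D array selecting in-mask voxels
#'   (default: all voxels).
#' @return An object of class `synthetic_fmri`: list with 4D `data`, 3D
#'   integer `mask`, integer `community_labels` (one per in-mask voxel, in
#'   column-major mask order), `within_r`, `between_r`.
#' @export
simulate_fmri_blocks <- function(shape, n_timepoints, n_communities = 2,
                                 within_r = 0.6, between_r = 0.1, seed = NULL,
                                 mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three positive extents")
  if (n_timepoints < 2L) stop("`n_timepoints` must be at least 2")
  if (!(between_r >= 0 && within_r >= between_r && within_r < 1))
    stop("need 0 <= between_r <= within_r < 1")
  if (within_r == between_r && within_r > 0)
    stop("within_r must exceed between_r (or both be 0)")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (is.null(mask)) mask <- array(1L, shape)
  mask <- array(as.integer(mask != 0), shape)
  vox <- which(mask == 1L)
  V <- length(vox)
  if (V < n_communities) stop("mask has fewer voxels than communities")
  labels <- rep(seq_len(n_communities), length.out = V)
  labels <- sort(labels)                      # contiguous equal-size blocks
  Tn <- n_timepoints
  # latent factors orthonormalised in-sample, so the realised factor
  # correlation matrix hits the target exactly (voxel noise still random)
  g0 <- as.vector(scale(stats::rnorm(Tn)))
  b <- if (within_r > 0) between_r / within_r else 0
  fac <- sapply(seq_len(n_communities), function(k) {
    e <- stats::rnorm(Tn)
    e <- e - g0 * sum(e * g0) / sum(g0 * g0)
    e <- as.vector(scale(e))
    sqrt(b) * g0 + sqrt(1 - b) * e
  })
  ts <- sqrt(within_r) * fac[, labels, drop = FALSE] +
    sqrt(1 - within_r) * matrix(stats::rnorm(Tn * V), Tn, V)
  data <- array(0, c(shape, Tn))
  flat <- matrix(data, ncol = Tn)
  flat[vox, ] <- t(ts)
  data <- array(flat, c(shape, Tn))
  structure(list(data = data, mask = mask, community_labels = labels,
                 within_r = within_r, between_r = between_r),
            class = "synthetic_fmri")
}

#' @export
print.synthetic_fmri <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<synthetic_fmri> %dx%dx%d x %d timepoints, %d in-mask voxels, %d communities\n",
              d[1], d[2], d[3], d[4], sum(x$mask), length(unique(x$community_labels))))
  invisible(x)
}
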