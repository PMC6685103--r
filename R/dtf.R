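#' Frequency-domain transfer matrix of an MVAR model
#'
#' Evaluates the lag polynomial A(f) = sum_{n=0..p} A_n exp(-j 2 pi f n / fs)
#' with A_0 = -I and inverts it to the transfer matrix H(f) = A(f)^-1 at
#' every grid frequency.
#'
#' @param model an [mvar()] fit (or any object with `coef` N x N x p array
#'   and `fs`), or a plain N x N x p coefficient array (then `fs` must be
#'   given).
#' @param freqs analysis frequencies in Hz (default 1--45 Hz in 0.5-Hz steps);
#'   all must be below fs/2.
#' @param fs sampling rate; taken from the model if present.
#' @return An object of class `spectral_transfer`: list with `freqs`, `H`
#'   (complex N x N x nf array), `A_of_f` (same shape), `fs`, `order`,
#'   `labels`.
#' @export
spectral_transfer <- function(model, freqs = seq(1, 45, by = 0.5), fs = NULL) {
  if (inherits(model, "mvar")) {
    A <- model$coef; fs <- model$fs; labels <- model$labels
    order <- model$order
  } else {
    A <- as_coef_array(model)
    if (is.null(fs)) stop("`fs` must be supplied with a plain coefficient array")
    labels <- dimnames(A)[[1]]
    order <- dim(A)[3]
  }
  if (any(freqs >= fs / 2) || any(freqs < 0))
    stop("all analysis frequencies must lie in [0, fs/2)")
  N <- dim(A)[1]; p <- dim(A)[3]; nf <- length(freqs)
  # lag polynomial with A_0 = -I; sign cancels in |H|^2
  coefs <- matrix(0, N * N, p + 1L)
  coefs[, 1L] <- as.vector(-diag(N))
  for (n in seq_len(p)) coefs[, n + 1L] <- as.vector(A[, , n])
  Emat <- exp(-2i * pi * outer(freqs / fs, 0:p))      # nf x (p+1)
  Af <- array(0i, c(N, N, nf)); Hf <- array(0i, c(N, N, nf))
  for (k in seq_len(nf)) {
    Ak <- matrix(coefs %*% Emat[k, ], N, N)
    Hk <- tryCatch(solve(Ak), error = function(e)
      stop(sprintf("A(f) is singular at f = %g Hz: %s", freqs[k],
                   conditionMessage(e)), call. = FALSE))
    Af[, , k] <- Ak; Hf[, , k] <- Hk
  }
  if (!is.null(labels)) {
    dimnames(Af) <- list(labels, labels, NULL)
    dimnames(Hf) <- list(labels, labels, NULL)
  }
  structure(list(freqs = freqs, H = Hf, A_of_f = Af, fs = fs,
                 order = order, labels = labels),
            class = "spectral_transfer")
}

#' @export
print.spectral_transfer <- function(x, ...) {
  cat(sprintf("<spectral_transfer> %d channels, %d frequencies (%g-%g Hz)\n",
              dim(x$H)[1], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Directed transfer function from a spectral transfer matrix
#'
#' gamma_ij(f)^2 = |H_ij(f)|^2 / sum_m |H_im(f)|^2: the share of inflow to
#' channel i contributed by channel j at frequency f.  Every row of gamma^2
#' sums to 1 at every frequency.
#'
#' @param st a [spectral_transfer()].
#' @param band length-2 Hz band over which [band_summary()] is taken
#'   (default gamma, 30--45 Hz).
#' @param include_diagonal should the scalar `dtf_mean` include the diagonal
#'   (self-inflow) terms?  Default `FALSE`: self-inflow dominates each row
#'   and would swamp the off-diagonal connectivity summary.
#' @return An object of class `dtf`: list with `gamma2` (N x N x nf, rows
#'   summing to 1 at each frequency), `freqs`, `band`, `band_mean` (N x N
#'   mean of gamma2 over band frequencies), `dtf_mean` (scalar mean of the
#'   off-diagonal band means), `labels`, `order`, `fs`.
#' @export
#' @examples
#' net <- matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE)
#' d <- dtf_from_transfer(spectral_transfer(net, fs = 128))
#' d$band_mean            # gamma_21^2 = 0.2 at every frequency
dtf_from_transfer <- function(st, band = c(30, 45), include_diagonal = FALSE) {
  stopifnot(inherits(st, "spectral_transfer"))
  N <- dim(st$H)[1]; nf <- length(st$freqs)
  g2 <- array(0, c(N, N, nf))
  for (k in seq_len(nf)) {
    Hm2 <- Mod(st$H[, , k])^2
    rs <- rowSums(Hm2)
    if (any(rs == 0))
      stop("all-zero transfer row at f = ", st$freqs[k],
           " Hz; transfer matrix is internally inconsistent")
    g2[, , k] <- Hm2 / rs
  }
  if (!is.null(st$labels)) dimnames(g2) <- list(st$labels, st$labels, NULL)
  res <- structure(list(gamma2 = g2, freqs = st$freqs, band = NULL,
                        band_mean = NULL, dtf_mean = NULL,
                        include_diagonal = include_diagonal,
                        labels = st$labels, order = st$order, fs = st$fs),
                   class = "dtf")
  bs <- band_summary(res, band, include_diagonal = include_diagonal)
  res$band <- bs$band; res$band_mean <- bs$band_mean; res$dtf_mean <- bs$dtf_mean
  res
}

#' Fit-to-DTF convenience wrapper
#'
#' Computes the spectral transfer of a fitted MVAR and its DTF in one call.
#'
#' @inheritParams spectral_transfer
#' @inheritParams dtf_from_transfer
#' @return A `dtf` object (see [dtf_from_transfer()]).
#' @export
dtf <- function(model, freqs = seq(1, 45, by = 0.5), band = c(30, 45),
                fs = NULL, include_diagonal = FALSE) {
  dtf_from_transfer(spectral_transfer(model, freqs = freqs, fs = fs),
                    band = band, include_diagonal = include_diagonal)
}

#' Band-average a DTF result
#'
#' @param res a `dtf` object.
#' @param band length-2 Hz limits (inclusive); must contain at least one
#'   grid frequency.
#' @param include_diagonal include diagonal terms in the scalar `dtf_mean`?
#' @return List with `band_mean` (N x N matrix averaged over band
#'   frequencies), `dtf_mean` (scalar mean over matrix elements, off-diagonal
#'   only unless `include_diagonal`), and `band`.
#' @export
band_summary <- function(res, band, include_diagonal = FALSE) {
  stopifnot(inherits(res, "dtf"), length(band) == 2L)
  sel <- res$freqs >= band[1] & res$freqs <= band[2]
  if (!any(sel))
    stop(sprintf("no grid frequency inside band (%g, %g) Hz", band[1], band[2]))
  bm <- apply(res$gamma2[, , sel, drop = FALSE], c(1, 2), mean)
  dm <- if (include_diagonal) mean(bm) else mean(offdiag_values(bm))
  list(band_mean = bm, dtf_mean = dm, band = band)
}

#' @export
print.dtf <- function(x, ...) {
  cat(sprintf("<dtf> %d channels, %d frequencies (%g-%g Hz), band %g-%g Hz\n",
              dim(x$gamma2)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              x$band[1], x$band[2]))
  cat(sprintf("  dtf_mean (off-diagonal band mean) = %.4f\n", x$dtf_mean))
  invisible(x)
}

#' Plot a band-mean DTF matrix
#'
#' @param x a `dtf` object.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.dtf <- function(x, main = sprintf("DTF band mean %g-%g Hz",
                                       x$band[1], x$band[2]), ...) {
  M <- x$band_mean
  N <- nrow(M)
  graphics::image(seq_len(N), seq_len(N), t(M[N:1, , drop = FALSE]),
                  axes = FALSE, xlab = "source j", ylab = "target i",
                  main = main, ...)
  labs <- if (is.null(x$labels)) seq_len(N) else x$labels
  graphics::axis(1, at = seq_len(N), labels = labs, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(N), labels = rev(labs), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Export a DTF result as long-format CSV
#'
#' Writes one row per (source, target, frequency) with the gamma^2 value,
#' plus a companion band-summary matrix CSV when `band_path` is given.
#'
#' @param res a `dtf` object.
#' @param path output CSV path.
#' @param band_path optional path for the band-mean matrix CSV.
#' @return `path`, invisibly.
#' @export
write_dtf_csv <- function(res, path, band_path = NULL) {
  stopifnot(inherits(res, "dtf"))
  N <- dim(res$gamma2)[1]
  labs <- if (is.null(res$labels)) as.character(seq_len(N)) else res$labels
  grid <- expand.grid(target = seq_len(N), source = seq_len(N),
                      frequency = res$freqs)
  out <- data.frame(source = labs[grid$source], target = labs[grid$target],
                    frequency = grid$frequency,
                    gamma2 = as.vector(res$gamma2))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(band_path)) {
    bm <- res$band_mean
    dimnames(bm) <- list(labs, labs)
    utils::write.csv(bm, band_path)
  }
  invisible(path)
}
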