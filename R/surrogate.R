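#' Surrogate-data null distribution of band-mean DTF
#'
#' Destroys cross-channel temporal structure by independently permuting each
#' channel's samples (within epochs, when the recording is epoched), then
#' refits the MVAR at the fixed observed order and recomputes the band-mean
#' DTF for every directed link.  Repeating this `n_shuffles` times yields the
#' empirical null distribution of each link's DTF under "no connectivity".
#'
#' @param rec the (conditioned, epoched) [eeg_recording()] under analysis.
#' @param order MVAR order, held fixed at the observed-data selection.
#' @param freqs analysis frequency grid (Hz), as used for the observed DTF.
#' @param band length-2 Hz band of the summary statistic.
#' @param n_shuffles number of surrogates (default 1000); values below 100
#'   trigger a warning about quantile resolution.
#' @param alpha default significance level carried to [prune()].
#' @param seed integer seed; results are deterministic given the seed.
#' @return An object of class `surrogate_null`: list with `null_values`
#'   (N x N x n_shuffles array of band-mean gamma^2 under shuffling; diagonal
#'   `NA`), `n_shuffles`, `alpha`, `seed`, `order`, `freqs`, `band`,
#'   `labels`, `n_retries` (surrogates refit after an estimation failure).
#' @export
surrogate_null <- function(rec, order, freqs = seq(1, 45, by = 0.5),
                           band = c(30, 45), n_shuffles = 1000,
                           alpha = 0.05, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), order >= 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (n_shuffles < 100)
    warning("n_shuffles = ", n_shuffles,
            " gives coarse null quantiles; 100 or more recommended")
  band_freqs <- freqs[freqs >= band[1] & freqs <= band[2]]
  if (length(band_freqs) == 0)
    stop(sprintf("no grid frequency inside band (%g, %g) Hz", band[1], band[2]))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  N <- nrow(rec$data)
  bounds <- epoch_bounds(rec)
  X <- rec$data - rowMeans(rec$data)
  null_values <- array(NA_real_, c(N, N, n_shuffles))
  n_retries <- 0L
  for (s in seq_len(n_shuffles)) {
    repeat {
      Xs <- shuffle_channels(X, bounds)
      bm <- tryCatch({
        fc <- fit_core(Xs, order, bounds, rec$labels, coefficients_only = TRUE)
        band_mean_from_coef(fc$A, rec$fs, band_freqs)
      }, error = function(e) NULL)
      if (!is.null(bm)) break
      n_retries <- n_retries + 1L
      if (n_retries > n_shuffles)
        stop("surrogate MVAR estimation failed repeatedly (",
             n_retries, " retries)")
    }
    diag(bm) <- NA_real_
    null_values[, , s] <- bm
  }
  structure(list(null_values = null_values, n_shuffles = n_shuffles,
                 alpha = alpha, seed = seed, order = order, freqs = freqs,
                 band = band, labels = rec$labels, n_retries = n_retries),
            class = "surrogate_null")
}

# Independent permutation of each channel's samples, within epochs.
shuffle_channels <- function(X, bounds) {
  N <- nrow(X)
  for (b in bounds) {
    idx <- b[1]:b[2]
    len <- length(idx)
    for (i in seq_len(N))
      X[i, idx] <- X[i, idx[sample.int(len)]]
  }
  X
}

# Band-mean gamma^2 straight from a coefficient array; identical in value to
# dtf() followed by band_summary() restricted to these frequencies (the band
# mean only involves in-band grid points).  Kept lean for the surrogate loop.
band_mean_from_coef <- function(A, fs, band_freqs) {
  N <- dim(A)[1]; p <- dim(A)[3]
  coefs <- matrix(0, N * N, p + 1L)
  coefs[, 1L] <- as.vector(-diag(N))
  for (n in seq_len(p)) coefs[, n + 1L] <- as.vector(A[, , n])
  Emat <- exp(-2i * pi * outer(band_freqs / fs, 0:p))
  acc <- matrix(0, N, N)
  for (k in seq_along(band_freqs)) {
    Hm2 <- Mod(solve(matrix(coefs %*% Emat[k, ], N, N)))^2
    acc <- acc + Hm2 / rowSums(Hm2)
  }
  acc / length(band_freqs)
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %d shuffles, order %d, band %g-%g Hz, alpha %g\n",
              x$n_shuffles, x$order, x$band[1], x$band[2], x$alpha))
  if (x$n_retries > 0) cat("  ", x$n_retries, "surrogate(s) retried\n")
  invisible(x)
}

#' Prune non-significant DTF links against a surrogate null
#'
#' A directed link is kept when its observed band-mean gamma^2 exceeds the
#' empirical (1 - alpha) quantile of its surrogate null.  Empirical p-values
#' use the add-one estimator p = (1 + #\{null >= observed\}) / (1 + n_shuffles),
#' so p is never exactly zero.
#'
#' @param observed a `dtf` object from the observed recording.
#' @param null a [surrogate_null()] built under the identical configuration
#'   (same order, frequency grid and band) -- mismatches are a hard error.
#' @param alpha significance level; defaults to the level stored in `null`.
#' @param adjust `"none"` (default, per-link test) or `"BH"` for
#'   Benjamini-Hochberg correction across links (selection then uses
#'   adjusted p <= alpha).
#' @return An object of class `dtf_pruned`: list with `keep` (logical N x N,
#'   diagonal `NA`), `p_values` (N x N, diagonal `NA`), `dtf` (the observed
#'   `dtf` with non-significant off-diagonal band means set to 0 and
#'   `dtf_mean` recomputed), `alpha`, `adjust`, `labels`, `band`, `order`.
#' @export
prune <- function(observed, null, alpha = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(observed, "dtf"), inherits(null, "surrogate_null"))
  adjust <- match.arg(adjust)
  if (is.null(alpha)) alpha <- null$alpha
  if (!isTRUE(all.equal(observed$band, null$band)))
    stop("configuration mismatch: observed band (",
         paste(observed$band, collapse = "-"), ") differs from null band (",
         paste(null$band, collapse = "-"), ")")
  if (!is.null(observed$order) && observed$order != null$order)
    stop("configuration mismatch: observed MVAR order ", observed$order,
         " differs from null order ", null$order)
  if (!isTRUE(all.equal(observed$freqs, null$freqs)))
    stop("configuration mismatch: frequency grids differ")
  N <- dim(observed$band_mean)[1]
  obs <- observed$band_mean
  ns <- null$n_shuffles
  keep <- matrix(NA, N, N)
  pv <- matrix(NA_real_, N, N)
  kq <- ceiling((1 - alpha) * ns)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    nv <- sort(null$null_values[i, j, ])
    pv[i, j] <- (1 + sum(nv >= obs[i, j])) / (1 + ns)
    keep[i, j] <- obs[i, j] > nv[kq]
  }
  if (adjust == "BH") {
    off <- row(pv) != col(pv)
    padj <- pv
    padj[off] <- stats::p.adjust(pv[off], method = "BH")
    keep[off] <- padj[off] <= alpha
    pv <- padj
  }
  pruned <- observed
  bm <- obs
  bm[which(!keep)] <- 0
  pruned$band_mean <- bm
  pruned$dtf_mean <- if (isTRUE(observed$include_diagonal)) mean(bm)
                     else mean(offdiag_values(bm))
  if (!is.null(null$labels)) dimnames(keep) <- dimnames(pv) <-
      list(null$labels, null$labels)
  structure(list(keep = keep, p_values = pv, dtf = pruned, alpha = alpha,
                 adjust = adjust, labels = null$labels, band = null$band,
                 order = null$order),
            class = "dtf_pruned")
}

#' @export
print.dtf_pruned <- function(x, ...) {
  nk <- sum(x$keep, na.rm = TRUE)
  cat(sprintf("<dtf_pruned> %d of %d links significant at alpha = %g (band %g-%g Hz)\n",
              nk, sum(!is.na(x$keep)), x$alpha, x$band[1], x$band[2]))
  cat(sprintf("  pruned dtf_mean = %.4f\n", x$dtf$dtf_mean))
  invisible(x)
}

#' Serialize a surrogate analysis to a results directory
#'
#' Writes per-link null quantiles and p-values as CSV plus a JSON summary
#' carrying the seed and configuration, sufficient to reproduce the run.
#'
#' @param pruned a [prune()] result.
#' @param null the matching [surrogate_null()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_surrogate_results <- function(pruned, null, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- dim(null$null_values)[1]
  labs <- if (is.null(null$labels)) as.character(seq_len(N)) else null$labels
  off <- which(row(diag(N)) != col(diag(N)), arr.ind = TRUE)
  q95 <- apply(null$null_values, c(1, 2), stats::quantile, probs = 0.95,
               na.rm = TRUE, names = FALSE)
  links <- data.frame(
    source = labs[off[, 2]], target = labs[off[, 1]],
    pruned_value = pruned$dtf$band_mean[off],
    p_value = pruned$p_values[off],
    null_q95 = q95[off],
    significant = pruned$keep[off])
  utils::write.csv(links, file.path(dir, "links.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_shuffles = null$n_shuffles, alpha = pruned$alpha,
         adjust = pruned$adjust, seed = null$seed, order = null$order,
         band = null$band, n_retries = null$n_retries,
         n_significant = sum(pruned$keep, na.rm = TRUE)),
    file.path(dir, "surrogate_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
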