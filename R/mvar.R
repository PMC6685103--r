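#' Fit a multivariate autoregressive (MVAR) model
#'
#' Least-squares estimation of X(t) = sum_{n=1..p} A_n X(t-n) + E(t) on a
#' (possibly epoched) multichannel recording.  Channels are demeaned before
#' regression; with epoched data the normal equations are pooled across
#' epochs and no lag window crosses an epoch boundary.  If `order` is `NULL`
#' the order is chosen by [select_order()] over `order_range` first.
#'
#' @param rec an [eeg_recording()].
#' @param order model order p, or `NULL` for data-driven selection.
#' @param order_range length-2 search range for the order (default `c(1, 20)`).
#' @param criterion `"SBC"` (Schwarz's Bayesian Criterion, default) or
#'   `"FPE"` (log final prediction error) for order selection.
#' @return An object of class `mvar`: list with `coef` (N x N x p array;
#'   `coef[i, j, n]` is the lag-n influence of channel j on channel i),
#'   `noise_cov` (residual covariance with small-sample divisor
#'   `ne - N p - 1`), `order`, `n_samples_used` (regression rows `ne`),
#'   `sbc`, `fpe`, `labels`, `fs`, `residuals`, and `order_selection`
#'   (criterion curve, when selection ran).
#' @seealso [select_order()], [spectral_transfer()], [dtf()]
#' @export
#' @examples
#' net <- mvar_network(matrix(c(0.3, 0, 0.5, 0.3), 2, 2, byrow = TRUE))
#' rec <- simulate_mvar(net, 2000, seed = 1)
#' fit <- mvar(rec, order = 1)
#' round(coef(fit)[, , 1], 2)
mvar <- function(rec, order = NULL, order_range = c(1, 20),
                 criterion = c("SBC", "FPE")) {
  stopifnot(inherits(rec, "eeg_recording"))
  criterion <- match.arg(criterion)
  sel <- NULL
  if (is.null(order)) {
    sel <- select_order(rec, p_min = order_range[1], p_max = order_range[2],
                        criterion = criterion)
    order <- sel$order
  }
  if (order < 1) stop("`order` must be at least 1")
  bounds <- epoch_bounds(rec)
  order <- as.integer(order)
  ne <- sum(vapply(bounds, function(b) max(0L, b[2] - b[1] + 1L - order),
                   numeric(1)))
  N <- nrow(rec$data)
  if (ne <= N * order + 1L)
    stop("not enough samples (", ne, " regression rows) to fit ",
         N, " channels at order ", order)
  mu <- rowMeans(rec$data)
  fitc <- fit_core(rec$data - mu, order, bounds, rec$labels)
  crit <- order_criteria(fitc$rss_logdet, N, fitc$ne, order)
  structure(list(coef = fitc$A, noise_cov = fitc$noise_cov, order = order,
                 n_samples_used = fitc$ne, sbc = crit["sbc"],
                 fpe = crit["fpe"], labels = rec$labels, fs = rec$fs,
                 channel_means = mu, residuals = fitc$residuals,
                 order_selection = sel, call = match.call()),
            class = "mvar")
}

#' Select the MVAR model order by SBC or FPE
#'
#' Fits the lagged regression at every order in `[p_min, p_max]` on a common
#' set of regression rows (those valid at `p_max`, so criteria are computed
#' on identical data) and returns the order minimising the chosen criterion
#' together with the full criterion curve.
#'
#' The criteria follow the standard ARfit approximations: with m channels,
#' ne regression rows, np = m * p parameters per output and D_p the residual
#' cross-product matrix,
#' `SBC(p) = logdet(D_p)/m - log(ne) * (ne - np)/ne` and
#' `FPE(p) = logdet(D_p)/m - log(ne * (ne - np) / (ne + np))`.
#'
#' @param rec an [eeg_recording()].
#' @param p_min,p_max inclusive order search range.
#' @param criterion `"SBC"` or `"FPE"`.
#' @return List with `order` (selected p), `criterion`, and `criteria`
#'   (data.frame of order, sbc, fpe).
#' @export
select_order <- function(rec, p_min = 1, p_max = 20,
                         criterion = c("SBC", "FPE")) {
  stopifnot(inherits(rec, "eeg_recording"))
  criterion <- match.arg(criterion)
  if (p_min > p_max) stop("`p_min` (", p_min, ") exceeds `p_max` (", p_max, ")")
  if (p_min < 1) stop("`p_min` must be at least 1")
  N <- nrow(rec$data)
  n <- ncol(rec$data)
  if (p_max * N >= n / 10)
    stop("identifiability guard: p_max * N = ", p_max * N,
         " must be below n_samples / 10 = ", n / 10)
  bounds <- epoch_bounds(rec)
  X <- rec$data - rowMeans(rec$data)
  # one design at p_max; order p uses its first N*p columns (lag-major)
  d <- lag_design(X, p_max, bounds)
  orders <- p_min:p_max
  crit <- t(vapply(orders, function(p) {
    Zp <- d$Z[, seq_len(N * p), drop = FALSE]
    qz <- qr_checked(Zp, rec$labels, N)
    Eres <- d$Y - Zp %*% qr.coef(qz, d$Y)
    order_criteria(logdet_crossprod(Eres), N, nrow(d$Y), p)
  }, c(sbc = 0, fpe = 0)))
  curve <- data.frame(order = orders, sbc = crit[, "sbc"], fpe = crit[, "fpe"])
  sel <- orders[which.min(if (criterion == "SBC") curve$sbc else curve$fpe)]
  list(order = sel, criterion = criterion, criteria = curve)
}

# ---- internals -------------------------------------------------------------

# Pooled lagged design over epochs.  Columns of Z are lag-major:
# [lag1 ch1..chN, lag2 ch1..chN, ...].  X is channels x samples, demeaned.
lag_design <- function(X, p, bounds) {
  Ys <- list(); Zs <- list()
  k <- 0L
  for (b in bounds) {
    len <- b[2] - b[1] + 1L
    if (len <= p) next
    t_idx <- (b[1] + p):b[2]
    k <- k + 1L
    Ys[[k]] <- t(X[, t_idx, drop = FALSE])
    Zs[[k]] <- do.call(cbind, lapply(seq_len(p), function(n)
      t(X[, t_idx - n, drop = FALSE])))
  }
  if (k == 0L) stop("no epoch is longer than the model order")
  list(Y = do.call(rbind, Ys), Z = do.call(rbind, Zs))
}

qr_checked <- function(Z, labels, N) {
  qz <- qr(Z, LAPACK = TRUE)
  rd <- abs(diag(qr.R(qz)))
  if (any(rd < max(rd) * 1e-10)) {
    bad <- sort(unique((qz$pivot[rd < max(rd) * 1e-10] - 1L) %% N + 1L))
    stop("rank-deficient lagged design (condition ratio ",
         format(max(rd) / min(rd), digits = 3), "); offending channel(s): ",
         paste(labels[bad], collapse = ", "))
  }
  qz
}

# Coefficient estimate + residual covariance for fixed order.
fit_core <- function(X, p, bounds, labels, coefficients_only = FALSE) {
  N <- nrow(X)
  d <- lag_design(X, p, bounds)
  qz <- qr_checked(d$Z, labels, N)
  B <- qr.coef(qz, d$Y)                      # (N p) x N
  A <- array(t(B), c(N, N, p))               # A[i, j, n] = B[(n-1)N + j, i]
  if (coefficients_only)
    return(list(A = A, ne = nrow(d$Y)))
  Eres <- d$Y - d$Z %*% B
  ne <- nrow(d$Y)
  S <- crossprod(Eres) / max(1L, ne - N * p - 1L)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(labels, labels)
  dimnames(A) <- list(labels, labels, NULL)
  list(A = A, noise_cov = S, residuals = Eres, ne = ne,
       rss_logdet = logdet_crossprod(Eres))
}

logdet_crossprod <- function(E) {
  R <- qr.R(qr(E, LAPACK = TRUE))
  2 * sum(log(abs(diag(R))))
}

# ARfit-style order-selection criteria (see select_order docs).
order_criteria <- function(logdp, m, ne, p) {
  ne <- as.numeric(ne)
  np <- m * p
  c(sbc = logdp / m - log(ne) * (ne - np) / ne,
    fpe = logdp / m - log(ne * (ne - np) / (ne + np)))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.mvar <- function(x, ...) {
  cat(sprintf("<mvar> %d channels, order %d, fitted on %d samples\n",
              dim(x$coef)[1], x$order, x$n_samples_used))
  cat(sprintf("  SBC %.4f, log-FPE %.4f, spectral radius %.3f\n",
              x$sbc, x$fpe, companion_radius(x$coef)))
  invisible(x)
}

#' @export
summary.mvar <- function(object, ...) {
  s <- list(order = object$order, n_channels = dim(object$coef)[1],
            ne = object$n_samples_used, sbc = object$sbc, fpe = object$fpe,
            radius = companion_radius(object$coef),
            noise_sd = sqrt(diag(object$noise_cov)),
            max_offdiag = max(abs(offdiag_values(apply(abs(object$coef),
                                                       c(1, 2), max)))),
            selection = object$order_selection)
  class(s) <- "summary.mvar"
  s
}

#' @export
print.summary.mvar <- function(x, ...) {
  cat(sprintf("MVAR(%d) on %d channels; %d regression rows\n",
              x$order, x$n_channels, x$ne))
  cat(sprintf("  SBC %.4f  log-FPE %.4f  spectral radius %.3f (stable: %s)\n",
              x$sbc, x$fpe, x$radius, x$radius < 1))
  cat(sprintf("  largest off-diagonal |coupling| %.3f\n", x$max_offdiag))
  cat("  residual sd per channel:\n")
  print(round(x$noise_sd, 3))
  if (!is.null(x$selection)) {
    cat(sprintf("  order selected by %s over [%d, %d]\n", x$selection$criterion,
                min(x$selection$criteria$order), max(x$selection$criteria$order)))
  }
  invisible(x)
}

#' @export
coef.mvar <- function(object, ...) object$coef

#' @export
residuals.mvar <- function(object, ...) object$residuals

#' One-step-ahead predictions from a fitted MVAR
#'
#' @param object an [mvar()] fit.
#' @param newdata an [eeg_recording()] with the same channels; defaults to
#'   nothing (there is no stored data to refit).
#' @param ... unused.
#' @return Channels x samples matrix of one-step predictions (the first
#'   `order` columns are `NA`).
#' @export
predict.mvar <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "eeg_recording"))
  if (nrow(newdata$data) != dim(object$coef)[1])
    stop("newdata channel count does not match the fitted model")
  X <- newdata$data - object$channel_means
  p <- object$order; N <- nrow(X); n <- ncol(X)
  pred <- matrix(NA_real_, N, n, dimnames = list(object$labels, NULL))
  Astack <- matrix(aperm(object$coef, c(1, 3, 2)), nrow = N)
  for (t in (p + 1L):n) {
    xlag <- X[, (t - 1L):(t - p), drop = FALSE]
    pred[, t] <- Astack %*% as.vector(t(xlag)) + object$channel_means
  }
  pred
}

#' Simulate new data from a fitted MVAR
#'
#' Treats the fitted coefficients as a generating network with independent
#' Gaussian innovations whose standard deviations are the square roots of
#' the diagonal of the residual covariance (off-diagonal residual covariance
#' is not reproduced).
#'
#' @param object an [mvar()] fit.
#' @param nsim number of samples to generate.
#' @param seed integer seed.
#' @param ... passed to [simulate_mvar()] (e.g. `burn_in`).
#' @return An [eeg_recording()].
#' @export
simulate.mvar <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_mvar(as_network(object), n_samples = nsim, fs = object$fs,
                seed = seed, ...)
}

#' Convert a fitted MVAR into a ground-truth network object
#'
#' @param model an [mvar()] fit.
#' @return An [mvar_network()] with the fitted coefficients and the residual
#'   standard deviations as innovation scales.
#' @export
as_network <- function(model) {
  stopifnot(inherits(model, "mvar"))
  mvar_network(model$coef, noise_sd = sqrt(diag(model$noise_cov)),
               labels = model$labels)
}

#' Is a fitted MVAR (or network) stable?
#'
#' @param x an `mvar` fit or `mvar_network`.
#' @return `TRUE` if the companion spectral radius is below 1.
#' @export
is_stable <- function(x) {
  A <- if (inherits(x, "mvar")) x$coef else x$coupling
  companion_radius(A) < 1
}

offdiag_values <- function(M) M[row(M) != col(M)]
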