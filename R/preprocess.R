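#' Condition a recording: low-pass, notch, polynomial baseline removal
#'
#' Applies zero-phase (forward-backward) Butterworth filters -- an order-4
#' low-pass and an order-2 band-stop notch -- followed by per-channel removal
#' of a fitted polynomial trend.  Zero-phase filtering preserves the temporal
#' structure the MVAR stage depends on (no group delay).
#'
#' @param rec an [eeg_recording()].
#' @param lowpass_hz low-pass cutoff (Hz); `NULL` skips the low-pass.
#' @param notch_band length-2 band edges (Hz) of the stop band; `NULL` skips
#'   the notch.
#' @param baseline_poly_order polynomial order for baseline correction
#'   (default 3); `0` removes the mean only, `NULL` skips it.
#' @return The conditioned recording; a `conditioning` attribute records the
#'   settings applied.
#' @export
condition <- function(rec, lowpass_hz = 100, notch_band = c(49, 51),
                      baseline_poly_order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!is.null(lowpass_hz) && lowpass_hz >= nyq)
    stop(sprintf("low-pass cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 lowpass_hz, nyq))
  if (!is.null(notch_band)) {
    if (length(notch_band) != 2L || notch_band[1] >= notch_band[2])
      stop("`notch_band` must be increasing (lo, hi)")
    if (notch_band[1] <= 0 || notch_band[2] >= nyq)
      stop(sprintf("notch band (%g, %g) Hz must lie strictly inside (0, %g) Hz",
                   notch_band[1], notch_band[2], nyq))
  }
  X <- rec$data
  if (!is.null(lowpass_hz)) {
    flt <- signal::butter(4, lowpass_hz / nyq, type = "low")
    X <- t(apply(X, 1L, function(ch) signal::filtfilt(flt, ch)))
  }
  if (!is.null(notch_band)) {
    flt <- signal::butter(2, notch_band / nyq, type = "stop")
    X <- t(apply(X, 1L, function(ch) signal::filtfilt(flt, ch)))
  }
  if (!is.null(baseline_poly_order))
    X <- t(apply(X, 1L, remove_baseline, order = baseline_poly_order))
  out <- rec
  out$data <- X
  rownames(out$data) <- rec$labels
  attr(out, "conditioning") <- list(lowpass_hz = lowpass_hz,
                                    notch_band = notch_band,
                                    baseline_poly_order = baseline_poly_order)
  out
}

# Subtract the least-squares polynomial of the given order from a vector.
remove_baseline <- function(x, order) {
  n <- length(x)
  if (order == 0) return(x - mean(x))
  basis <- cbind(1, stats::poly(seq_len(n), degree = order))
  x - basis %*% qr.coef(qr(basis), x)
}

#' Drop epochs with out-of-range amplitudes
#'
#' A simple amplitude-threshold artifact screen: any epoch containing a sample
#' whose absolute value exceeds `amplitude_limit` is dropped whole.  The
#' recording must be epoched first.
#'
#' @param rec an epoched [eeg_recording()].
#' @param amplitude_limit rejection threshold in the recording's units
#'   (default 100, i.e. +/-100 microvolts).
#' @return The recording with offending epochs removed; attribute
#'   `rejection_log` holds the dropped epoch indices and the limit used.
#' @export
reject_artifacts <- function(rec, amplitude_limit = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (amplitude_limit <= 0) stop("`amplitude_limit` must be positive")
  if (is.null(rec$epoch_samples))
    stop("recording must be epoched (see epoch_recording()) before artifact rejection")
  bounds <- epoch_bounds(rec)
  bad <- vapply(bounds, function(b)
    any(abs(rec$data[, b[1]:b[2]]) > amplitude_limit), logical(1))
  if (all(bad))
    stop("all ", length(bad), " epochs exceed the amplitude limit of ",
         amplitude_limit, "; no data left")
  keep_cols <- unlist(lapply(bounds[!bad], function(b) b[1]:b[2]))
  out <- rec
  out$data <- rec$data[, keep_cols, drop = FALSE]
  out$n_epochs <- sum(!bad)
  attr(out, "rejection_log") <- list(dropped = which(bad),
                                     n_dropped = sum(bad),
                                     amplitude_limit = amplitude_limit)
  out
}

#' Per-channel signal-to-noise ratio
#'
#' SNR of channel i is the variance ratio sd_signal(i)^2 / sd_noise(i)^2,
#' with the noise standard deviation estimated from a designated quiet
#' ("pre") interval of the recording and the signal standard deviation taken
#' over the whole recording.
#'
#' @param rec an [eeg_recording()].
#' @param noise_interval `(start_s, end_s)` of the noise-estimation interval,
#'   in seconds from recording onset (default first second).
#' @return An object of class `snr_report`: list with `per_channel_snr`,
#'   `noise_sd_estimate`, `signal_sd`, `noise_interval`.
#' @export
compute_snr <- function(rec, noise_interval = c(0, 1)) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- ncol(rec$data) / rec$fs
  if (length(noise_interval) != 2L || noise_interval[1] < 0 ||
      noise_interval[2] > dur || noise_interval[1] >= noise_interval[2])
    stop(sprintf("noise interval (%g, %g) s must lie inside the recording (0, %g) s",
                 noise_interval[1], noise_interval[2], dur))
  i0 <- max(1L, floor(noise_interval[1] * rec$fs) + 1L)
  i1 <- min(ncol(rec$data), ceiling(noise_interval[2] * rec$fs))
  noise_sd <- apply(rec$data[, i0:i1, drop = FALSE], 1L, stats::sd)
  if (any(noise_sd == 0))
    stop("zero-variance noise interval for channel(s): ",
         paste(rec$labels[noise_sd == 0], collapse = ", "))
  signal_sd <- apply(rec$data, 1L, stats::sd)
  snr <- (signal_sd / noise_sd)^2
  names(snr) <- rec$labels
  structure(list(per_channel_snr = snr, noise_sd_estimate = noise_sd,
                 signal_sd = signal_sd, noise_interval = noise_interval),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat("<snr_report> variance-ratio SNR per channel\n")
  print(round(x$per_channel_snr, 2))
  invisible(x)
}

#' Gate channels on their SNR
#'
#' Flags which channels fall inside a working SNR range.  The range is a
#' quality gate, not a hard filter: the function reports, it does not drop.
#'
#' @param report an [compute_snr()] report.
#' @param lower,upper inclusive SNR bounds (defaults 7 and Inf).
#' @return List with logical `pass` per channel, the bounds, and the labels
#'   of failing channels.
#' @export
snr_gate <- function(report, lower = 7, upper = Inf) {
  stopifnot(inherits(report, "snr_report"), lower >= 0, upper > lower)
  snr <- report$per_channel_snr
  pass <- snr >= lower & snr <= upper
  list(pass = pass, lower = lower, upper = upper,
       failed = names(snr)[!pass])
}
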