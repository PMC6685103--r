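#' Multichannel EEG recording
#'
#' Container for a channels-by-samples signal matrix with a sampling rate and
#' 10-20 channel labels.  All analysis functions in the package take and
#' return this class.
#'
#' @param data numeric matrix, channels x samples (microvolts by convention).
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel names; defaults to a
#'   standard 10-20 montage of the appropriate size (see [montage_1020()]).
#' @param unit signal unit label, stored for reporting only.
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs`, `labels`, `unit`, and (after [epoch_recording()]) `epoch_samples`
#'   and `n_epochs`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 100)
#' rec
eeg_recording <- function(data, fs, labels = NULL, unit = "uV") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  if (is.null(labels)) labels <- montage_1020(nrow(data))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels),
         ") does not match number of channels (", nrow(data), ")")
  if (anyDuplicated(labels))
    stop("channel labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, unit = unit,
                 epoch_samples = NULL, n_epochs = NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$labels, 8L), collapse = " "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  if (!is.null(x$epoch_samples))
    cat(sprintf("  epoched: %d epochs of %d samples (%.2f s)\n",
                x$n_epochs, x$epoch_samples, x$epoch_samples / x$fs))
  invisible(x)
}

#' @export
as.matrix.eeg_recording <- function(x, ...) x$data

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Cut a recording into non-overlapping epochs
#'
#' Trailing samples that do not fill a whole epoch are dropped.  Epoching only
#' marks boundaries; the data stay one contiguous matrix.  MVAR fitting and
#' surrogate shuffling respect the boundaries (no lag window crosses an epoch
#' edge; permutations stay within epochs).
#'
#' @param rec an [eeg_recording()].
#' @param epoch_length_s epoch length in seconds (default 2).
#' @return The recording with `epoch_samples` and `n_epochs` set.
#' @export
epoch_recording <- function(rec, epoch_length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- as.integer(round(epoch_length_s * rec$fs))
  if (len < 2L) stop("epoch length of ", epoch_length_s, " s gives fewer than 2 samples")
  n_ep <- ncol(rec$data) %/% len
  if (n_ep < 1L)
    stop("recording shorter (", ncol(rec$data), " samples) than one epoch (", len, ")")
  rec$data <- rec$data[, seq_len(n_ep * len), drop = FALSE]
  rec$epoch_samples <- len
  rec$n_epochs <- n_ep
  rec
}

# Column-index ranges of each epoch; a non-epoched recording is one epoch.
epoch_bounds <- function(rec) {
  if (is.null(rec$epoch_samples))
    return(list(c(1L, ncol(rec$data))))
  len <- rec$epoch_samples
  lapply(seq_len(rec$n_epochs), function(k) c((k - 1L) * len + 1L, k * len))
}

#' Standard 10-20 montage labels
#'
#' Returns the first `n` labels of a fixed 32-channel extended 10-20 layout
#' (the montage used throughout the package's examples and simulations).
#'
#' @param n number of channels (1--32).
#' @return Character vector of length `n`.
#' @export
montage_1020 <- function(n) {
  full <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6", "T3", "C3", "Cz", "C4", "T4",
            "CP5", "CP1", "CP2", "CP6", "T5", "P3", "Pz", "P4", "T6",
            "PO3", "POz", "PO4", "O1", "Oz", "O2", "A1")
  if (n > length(full))
    return(c(full, paste0("X", seq_len(n - length(full)))))
  full[seq_len(n)]
}

#' Posterior subset of the 32-channel montage
#'
#' The centro-parieto-occipital strip attenuated in the synthetic "patient"
#' of [replica_study()].
#'
#' @return Character vector of 10-20 labels.
#' @export
posterior_channels <- function() {
  c("CP5", "CP1", "CP2", "CP6", "T5", "P3", "Pz", "P4", "T6",
    "PO3", "POz", "PO4", "O1", "Oz", "O2")
}
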