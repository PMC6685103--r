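#' Write a recording as CSV (samples x channels)
#'
#' Columns are labelled channels, rows samples; the first line is a comment
#' header carrying the sampling rate and unit, e.g. `# fs=512 unit=uV`.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g unit=%s", rec$fs, rec$unit), con)
  utils::write.csv(as.data.frame(t(rec$data)), con, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV written by [write_recording_csv()]
#'
#' @param path input path.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*fs=", first))
    stop("not a recording CSV: missing `# fs=` header line in ", path)
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", first))
  unit <- if (grepl("unit=", first)) sub(".*unit=(\\S+).*", "\\1", first) else "uV"
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs = fs, labels = colnames(df), unit = unit)
}

# ---- minimal EDF I/O -------------------------------------------------------
# European Data Format: 256-byte fixed header + 256 bytes per signal, then
# sequential 1-second data records of little-endian int16 samples scaled
# between the declared physical and digital ranges.  Only the subset needed
# to round-trip continuous multichannel recordings is implemented.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording in EDF
#'
#' Uses 1-second data records; the recording is zero-padded to a whole
#' number of seconds and stored as 16-bit integers, so values are quantised
#' to the per-channel physical range over 65535 steps.  `fs` must be a whole
#' number.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  N <- nrow(rec$data); n <- ncol(rec$data)
  spr <- as.integer(fs)
  n_rec <- as.integer(ceiling(n / spr))
  X <- cbind(rec$data, matrix(0, N, n_rec * spr - n))
  pmax_ <- apply(abs(X), 1L, max)
  pmax_[pmax_ == 0] <- 1
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("synthetic recording", 80); wr("dtfnet export", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L * (1L + N), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(N, 4)
  # per-signal fields, written field-major per EDF layout
  fields <- list(list(16, function(i) rec$labels[i]),
                 list(80, function(i) ""),
                 list(8,  function(i) rec$unit),
                 list(8,  function(i) sprintf("%.7g", phys_min[i])),
                 list(8,  function(i) sprintf("%.7g", phys_max[i])),
                 list(8,  function(i) dig_min),
                 list(8,  function(i) dig_max),
                 list(80, function(i) ""),
                 list(8,  function(i) spr),
                 list(32, function(i) ""))
  for (fl in fields) for (i in seq_len(N)) wr(fl[[2]](i), fl[[1]])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(N)) {
      dig <- round((X[i, cols] - phys_min[i]) / scale[i]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads continuous EDF files with a uniform samples-per-record across
#' signals (the layout [write_edf()] produces and typical EEG exports use).
#'
#' @param path input path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  N <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(N), function(i) rd(width), character(1))
  labels <- fld(16); fld(80); unit <- fld(8)[1]
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stop("EDF files with differing samples-per-record per signal are not supported")
  spr <- spr[1]
  fs <- spr / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  X <- matrix(0, N, n_rec * spr)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(N)) {
      dig <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                     endian = "little")
      X[i, cols] <- (dig - dig_min[i]) * scale[i] + phys_min[i]
    }
  }
  eeg_recording(X, fs = fs, labels = labels, unit = unit)
}

# ---- MVAR model serialization ---------------------------------------------

#' Serialize a fitted MVAR model to JSON
#'
#' Stores coefficients, residual covariance, order, criteria and channel
#' metadata at full precision for pipeline checkpointing; residuals are not
#' stored.
#'
#' @param model an [mvar()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mvar_json <- function(model, path) {
  stopifnot(inherits(model, "mvar"))
  jsonlite::write_json(list(
    order = model$order,
    n_channels = dim(model$coef)[1],
    coef = as.vector(model$coef),        # column-major, dims (N, N, order)
    noise_cov = as.vector(model$noise_cov),
    n_samples_used = model$n_samples_used,
    sbc = unname(model$sbc), fpe = unname(model$fpe),
    labels = model$labels, fs = model$fs,
    channel_means = unname(model$channel_means)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted MVAR model from JSON
#'
#' @param path a file written by [write_mvar_json()].
#' @return An `mvar` object (without residuals).
#' @export
read_mvar_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- x$n_channels
  A <- array(as.numeric(x$coef), c(N, N, x$order))
  dimnames(A) <- list(x$labels, x$labels, NULL)
  S <- matrix(unlist(x$noise_cov), N, N)
  dimnames(S) <- list(x$labels, x$labels)
  structure(list(coef = A, noise_cov = S, order = x$order,
                 n_samples_used = x$n_samples_used, sbc = x$sbc, fpe = x$fpe,
                 labels = x$labels, fs = x$fs, channel_means = x$channel_means,
                 residuals = NULL, order_selection = NULL, call = NULL),
            class = "mvar")
}
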