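#' Pipeline configuration
#'
#' Collects every tunable setting of the EEG pipeline with the package
#' defaults: 100-Hz low-pass, 49--51-Hz notch, order-3 polynomial baseline,
#' 2-s epochs, +/-100 uV artifact limit, SBC order selection over [1, 20],
#' a 1--45 Hz grid in 0.5-Hz steps, a 30--45 Hz gamma band, 1000 surrogate
#' shuffles and link pruning at p < 0.05.  Settings are validated here, and
#' again (fast-fail) at the start of every pipeline run.
#'
#' @param lowpass_hz,notch_band,baseline_poly_order see [condition()].
#' @param epoch_length_s epoch length in seconds.
#' @param amplitude_limit artifact rejection threshold (recording units).
#' @param snr_gate length-2 working SNR range, reported per channel.
#' @param order fixed MVAR order, or `NULL` for selection.
#' @param order_range,criterion see [select_order()].
#' @param freqs analysis frequency grid (Hz).
#' @param bands named list of length-2 Hz bands; the first is the analysis
#'   band.
#' @param n_shuffles,alpha surrogate-test settings (link pruning level).
#' @param compare_alpha selection threshold of the electrode-wise group
#'   comparison (default 0.001).
#' @param profile_mode,test electrode-profile and comparison settings
#'   (see [electrode_profile()], [compare_profiles()]).
#' @param seed global integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(lowpass_hz = 100, notch_band = c(49, 51),
                            baseline_poly_order = 3, epoch_length_s = 2,
                            amplitude_limit = 100, snr_gate = c(7, 10),
                            order = NULL, order_range = c(1, 20),
                            criterion = "SBC",
                            freqs = seq(1, 45, by = 0.5),
                            bands = list(gamma = c(30, 45)),
                            n_shuffles = 1000, alpha = 0.05,
                            compare_alpha = 0.001,
                            profile_mode = "total", test = "auto",
                            seed = 1L) {
  cfg <- structure(list(
    lowpass_hz = lowpass_hz, notch_band = notch_band,
    baseline_poly_order = baseline_poly_order,
    epoch_length_s = epoch_length_s, amplitude_limit = amplitude_limit,
    snr_gate = snr_gate, order = order, order_range = order_range,
    criterion = criterion, freqs = freqs, bands = bands,
    n_shuffles = n_shuffles, alpha = alpha, compare_alpha = compare_alpha,
    profile_mode = profile_mode,
    test = test, seed = as.integer(seed)), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg, fs = NULL) {
  with(cfg, {
    if (alpha <= 0 || alpha >= 1) stop("config: alpha must be in (0, 1)")
    if (compare_alpha <= 0 || compare_alpha >= 1)
      stop("config: compare_alpha must be in (0, 1)")
    if (n_shuffles < 1) stop("config: n_shuffles must be positive")
    if (epoch_length_s <= 0) stop("config: epoch_length_s must be positive")
    if (amplitude_limit <= 0) stop("config: amplitude_limit must be positive")
    if (order_range[1] > order_range[2] || order_range[1] < 1)
      stop("config: invalid order_range")
    if (!profile_mode %in% c("total", "inflow", "outflow"))
      stop("config: unknown profile_mode ", profile_mode)
    if (!test %in% c("auto", "t", "wilcoxon"))
      stop("config: unknown test ", test)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      if (length(b) != 2L || b[1] >= b[2])
        stop("config: band `", bn, "` must be increasing (lo, hi)")
      if (!any(freqs >= b[1] & freqs <= b[2]))
        stop("config: band `", bn, "` (", b[1], "-", b[2],
             " Hz) contains no grid frequency")
    }
    if (!is.null(fs)) {
      if (!is.null(lowpass_hz) && lowpass_hz >= fs / 2)
        stop("config: low-pass cutoff ", lowpass_hz,
             " Hz not below Nyquist ", fs / 2, " Hz")
      if (max(freqs) >= fs / 2)
        stop("config: frequency grid exceeds Nyquist ", fs / 2, " Hz")
    }
  })
  invisible(cfg)
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips unchanged (up to numeric representation,
#' which `digits = NA` preserves exactly).
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bands <- lapply(x$bands, as.numeric)
  if (!is.null(x$order)) x$order <- as.integer(x$order)
  cfg <- structure(x[names(formals(pipeline_config))], class = "pipeline_config")
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  filters: low-pass %s Hz, notch %s Hz, baseline poly %s\n",
              format(x$lowpass_hz), paste(x$notch_band, collapse = "-"),
              format(x$baseline_poly_order)))
  cat(sprintf("  epochs %g s, artifact limit %g, SNR gate [%g, %g]\n",
              x$epoch_length_s, x$amplitude_limit, x$snr_gate[1], x$snr_gate[2]))
  cat(sprintf("  order: %s (%s over [%d, %d]); grid %g-%g Hz; band %s %g-%g Hz\n",
              if (is.null(x$order)) "auto" else x$order, x$criterion,
              x$order_range[1], x$order_range[2], min(x$freqs), max(x$freqs),
              names(x$bands)[1], x$bands[[1]][1], x$bands[[1]][2]))
  cat(sprintf("  %d shuffles, alpha %g, profile %s, test %s, seed %d\n",
              x$n_shuffles, x$alpha, x$profile_mode, x$test, x$seed))
  invisible(x)
}

# deterministic per-stage seed derivation (kept below 2^31; arithmetic in
# doubles to avoid integer overflow for large derived seeds)
stage_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483587)

#' Run the EEG connectivity pipeline on a set of recordings
#'
#' For each named recording: condition, epoch, artifact-reject, SNR report,
#' MVAR order selection and fit (pooled across epochs), DTF, surrogate null,
#' link pruning, and electrode profiles (subject level = mean of per-epoch
#' profiles; the per-epoch profiles are also returned).  When `roles` marks
#' recordings as `"control"` and `"patient"`, the patient's per-epoch
#' profiles are compared electrode-wise against the control subjects'
#' profiles.  All numeric outputs plus a provenance manifest (config, seeds,
#' package version, config file hash) are written to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param recordings named list of [eeg_recording()]s sharing one montage.
#' @param out_dir results directory (created).
#' @param roles optional named character vector mapping recording names to
#'   `"control"` or `"patient"`.
#' @return Invisibly, a list with per-recording results (`fits`, `dtf`,
#'   `pruned`, `snr`, `profiles`, `epoch_profiles`) and `comparison` (when
#'   roles given).
#' @export
run_eeg_pipeline <- function(config, recordings, out_dir, roles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(names(recordings)) || any(names(recordings) == ""))
    stop("`recordings` must be a named list")
  labs <- lapply(recordings, function(r) r$labels)
  if (length(unique(labs)) != 1L)
    stop("all recordings must share the same montage labels")
  for (r in recordings) validate_config(config, fs = r$fs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  band <- config$bands[[1]]
  res <- list()
  for (k in seq_along(recordings)) {
    name <- names(recordings)[k]
    r <- tryCatch({
      rec <- condition(recordings[[k]], config$lowpass_hz, config$notch_band,
                       config$baseline_poly_order)
      rec <- epoch_recording(rec, config$epoch_length_s)
      rec <- reject_artifacts(rec, config$amplitude_limit)
      snr <- compute_snr(rec)
      ord <- config$order
      sel <- NULL
      if (is.null(ord)) {
        sel <- select_order(rec, config$order_range[1], config$order_range[2],
                            config$criterion)
        ord <- sel$order
      }
      fit <- mvar(rec, order = ord)
      d <- dtf(fit, freqs = config$freqs, band = band)
      null <- surrogate_null(rec, order = ord, freqs = config$freqs,
                             band = band, n_shuffles = config$n_shuffles,
                             alpha = config$alpha,
                             seed = stage_seed(config$seed, k))
      pr <- prune(d, null, alpha = config$alpha)
      ep <- epoch_profiles(rec, pr, ord, config)
      prof <- rowMeans(ep)
      list(recording = rec, snr = snr, selection = sel, fit = fit, dtf = d,
           pruned = pr, profile = prof, epoch_profiles = ep,
           rejection = attr(rec, "rejection_log"))
    }, error = function(e)
      stop("pipeline stage failed for recording `", name, "`: ",
           conditionMessage(e), call. = FALSE))
    res[[name]] <- r
    write_dtf_csv(r$pruned$dtf, file.path(out_dir, paste0(name, "_dtf.csv")),
                  file.path(out_dir, paste0(name, "_band_mean.csv")))
    utils::write.csv(data.frame(electrode = names(r$profile),
                                value = unname(r$profile)),
                     file.path(out_dir, paste0(name, "_profile.csv")),
                     row.names = FALSE)
  }
  comparison <- NULL
  if (!is.null(roles)) {
    ctrl <- names(roles)[roles == "control"]
    pat <- names(roles)[roles == "patient"]
    if (length(ctrl) && length(pat)) {
      G <- sapply(res[ctrl], function(r) r$profile)
      S <- do.call(cbind, lapply(res[pat], function(r) r$epoch_profiles))
      comparison <- compare_profiles(G, S, alpha = config$compare_alpha,
                                     test = config$test)
      write_comparison(comparison, file.path(out_dir, "comparison.csv"))
    }
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  jsonlite::write_json(list(
    package = "dtfnet",
    version = as.character(utils::packageVersion("dtfnet")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    recordings = names(recordings),
    orders = vapply(res, function(r) r$fit$order, numeric(1))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, comparison = comparison, out_dir = out_dir))
}

# Per-epoch electrode profiles: each epoch's own MVAR + DTF band mean,
# masked by the recording-level significance decision.
epoch_profiles <- function(rec, pruned, ord, config) {
  bounds <- epoch_bounds(rec)
  band <- config$bands[[1]]
  band_freqs <- config$freqs[config$freqs >= band[1] & config$freqs <= band[2]]
  X <- rec$data - rowMeans(rec$data)
  sapply(seq_along(bounds), function(e) {
    fc <- fit_core(X, ord, bounds[e], rec$labels, coefficients_only = TRUE)
    bm <- band_mean_from_coef(fc$A, rec$fs, band_freqs)
    bm[which(!pruned$keep)] <- 0
    diag(bm) <- NA
    inflow <- rowMeans(bm, na.rm = TRUE)
    outflow <- colMeans(bm, na.rm = TRUE)
    vals <- switch(config$profile_mode, inflow = inflow, outflow = outflow,
                   total = (inflow + outflow) / 2)
    names(vals) <- rec$labels
    vals
  })
}

#' Run the GBC pipeline on 4D volumes
#'
#' Computes a GBC map per volume within its mask and, when two volumes share
#' a mask (e.g. pre/post), their descriptive difference map.  Maps, CSVs and
#' a manifest are written to `out_dir`.
#'
#' @param config a [pipeline_config()] (used for the seed/manifest only).
#' @param volume_paths named character vector of 4D NIfTI paths (or a named
#'   list of 4D arrays).
#' @param mask_paths a single mask path/array, or one per volume.
#' @param out_dir results directory.
#' @param min_timepoints passed to [gbc_map()].
#' @return Invisibly, list with `maps` and `differences`.
#' @export
run_gbc_pipeline <- function(config, volume_paths, mask_paths, out_dir,
                             min_timepoints = 10) {
  if (is.character(volume_paths)) {
    missing <- volume_paths[!file.exists(volume_paths)]
    if (length(missing))
      stop("volume path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  if (is.character(mask_paths)) {
    missing <- mask_paths[!file.exists(mask_paths)]
    if (length(missing))
      stop("mask path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  if (length(mask_paths) == 1L && length(volume_paths) > 1L)
    mask_paths <- rep(if (is.list(mask_paths)) mask_paths else
      list(mask_paths), length(volume_paths))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nm <- names(volume_paths)
  if (is.null(nm)) nm <- paste0("vol", seq_along(volume_paths))
  maps <- list()
  for (k in seq_along(volume_paths)) {
    vol <- volume_paths[[k]]
    msk <- if (is.list(mask_paths)) mask_paths[[k]] else mask_paths[[k]]
    if (is.character(msk)) msk <- as.array(RNifti::readNifti(msk))
    if (sum(msk != 0) == 0) stop("mask for `", nm[k], "` is empty")
    maps[[nm[k]]] <- gbc_map(vol, msk, min_timepoints = min_timepoints)
    write_gbc(maps[[nm[k]]],
              nifti_path = file.path(out_dir, paste0(nm[k], "_gbc.nii.gz")),
              csv_path = file.path(out_dir, paste0(nm[k], "_gbc.csv")))
  }
  differences <- NULL
  if (length(maps) == 2L) {
    differences <- compare_gbc(maps[[1]], maps[[2]])
    utils::write.csv(data.frame(voxel = differences$voxels,
                                difference = differences$difference),
                     file.path(out_dir, "gbc_difference.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(package = "dtfnet",
                            version = as.character(utils::packageVersion("dtfnet")),
                            seed = config$seed, volumes = nm),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(maps = maps, differences = differences))
}

#' Generate a patient-vs-controls synthetic study
#'
#' Builds a control-like 32-channel coupling network, derives per-control
#' networks by jittering coupling strengths, derives the "patient" network
#' by attenuating all couplings of the posterior electrodes, and simulates
#' one recording per subject.
#'
#' @param n_controls number of control subjects (default 8).
#' @param n_channels montage size (default 32).
#' @param duration_s recording length per subject in seconds.
#' @param fs sampling rate (Hz, default 256).
#' @param attenuation factor applied to posterior couplings of the patient.
#' @param coupling base off-diagonal coupling strength.
#' @param jitter between-subject coupling jitter half-width.
#' @param seed integer seed.
#' @return List with `controls` (named list of recordings), `patient`
#'   (recording), `network` (base [mvar_network()]), `patient_network`,
#'   `attenuated` (posterior channel labels).
#' @export
replica_study <- function(n_controls = 8, n_channels = 32, duration_s = 32,
                          fs = 256, attenuation = 0.15, coupling = 0.35,
                          jitter = 0.15, seed = 42) {
  base <- base_network(n_channels, coupling)
  attenuated <- intersect(posterior_channels(), base$labels)
  pat_net <- attenuate_couplings(base, attenuated, factor = attenuation)
  n <- round(duration_s * fs)
  controls <- list()
  for (k in seq_len(n_controls)) {
    net_k <- jitter_network(base, jitter = jitter,
                            seed = stage_seed(seed, 100L + k))
    controls[[sprintf("control%02d", k)]] <-
      simulate_mvar(net_k, n, fs = fs, seed = stage_seed(seed, 200L + k))
  }
  patient <- simulate_mvar(jitter_network(pat_net, jitter = jitter,
                                          seed = stage_seed(seed, 300L)),
                           n, fs = fs, seed = stage_seed(seed, 301L))
  list(controls = controls, patient = patient, network = base,
       patient_network = pat_net, attenuated = attenuated)
}

# Control-like base network: two coupling modules (anterior and posterior
# electrode groups), each a ring of neighbour couplings in montage order with
# AR(1) self terms.  Keeping the modules disconnected means a posterior
# "lesion" (attenuation) leaves anterior transfer functions untouched, so
# the study has unambiguous affected/unaffected ground truth.
base_network <- function(n_channels, coupling = 0.35) {
  N <- n_channels
  labels <- montage_1020(N)
  post <- which(labels %in% posterior_channels())
  groups <- list(setdiff(seq_len(N), post), post)
  A <- matrix(0, N, N)
  for (idx in groups) {
    m <- length(idx)
    if (m < 2L) next
    for (k in seq_len(m)) {
      A[idx[k], idx[if (k == 1L) m else k - 1L]] <- coupling
      A[idx[k], idx[if (k == m) 1L else k + 1L]] <- coupling / 2
    }
  }
  diag(A) <- 0.4
  rho <- companion_radius(array(A, c(N, N, 1)))
  if (rho >= 0.95) {
    d <- diag(A); A <- A * (0.9 / rho); diag(A) <- d
    while (companion_radius(array(A, c(N, N, 1))) >= 0.95) A <- A * 0.95
  }
  mvar_network(A, labels = labels)
}
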