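#' Voxelwise global brain connectivity within a mask
#'
#' For every voxel inside the binary mask, computes the mean Pearson
#' correlation of its time series with the time series of every other
#' in-mask voxel (self-correlation excluded).  Time series are linearly
#' detrended first; correlations are averaged raw by default (a Fisher-z
#' averaging flag is available).
#'
#' @param volume 4D numeric array (x, y, z, time), or a path to a 4D NIfTI.
#' @param mask 3D array (nonzero = in mask) of matching spatial extents, or
#'   a path to a 3D NIfTI.
#' @param min_timepoints smallest accepted number of volumes (default 10).
#' @param detrend remove a per-voxel linear trend first (default `TRUE`).
#' @param fisher_z average Fisher-z-transformed correlations and transform
#'   back (default `FALSE`: plain averaging of r).
#' @param mask_name label stored with the result (e.g. `"DMN"`, `"ECN"`).
#' @return An object of class `gbc_map`: list with `values` (one mean
#'   correlation per in-mask voxel, `NA` for constant voxels), `voxels`
#'   (their linear indices in the mask volume), `mask`, `mask_name`,
#'   `n_voxels`, `n_timepoints`, `excluded` (indices of constant voxels).
#' @export
gbc_map <- function(volume, mask, min_timepoints = 10, detrend = TRUE,
                    fisher_z = FALSE, mask_name = "custom") {
  if (is.character(volume)) volume <- as.array(RNifti::readNifti(volume))
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  dv <- dim(volume)
  if (length(dv) != 4L) stop("`volume` must be 4D (x, y, z, time)")
  dm <- dim(mask)
  if (length(dm) != 3L || any(dm != dv[1:3]))
    stop("mask extents (", paste(dm, collapse = "x"),
         ") do not match volume extents (", paste(dv[1:3], collapse = "x"), ")")
  vox <- which(mask != 0)
  if (length(vox) < 2L) stop("mask selects fewer than 2 voxels")
  Tn <- dv[4]
  if (Tn < min_timepoints)
    stop("volume has ", Tn, " timepoints; at least ", min_timepoints, " required")
  ts <- t(matrix(volume, ncol = Tn)[vox, , drop = FALSE])   # T x V
  flat_voxel <- apply(ts, 2L, function(v) diff(range(v)) == 0)
  if (detrend) {
    tt <- seq_len(Tn)
    ts <- stats::lm.fit(cbind(1, tt), ts)$residuals
  }
  sds <- apply(ts, 2L, stats::sd)
  valid <- !flat_voxel & sds > 0
  values <- rep(NA_real_, length(vox))
  if (sum(valid) >= 2L) {
    C <- stats::cor(ts[, valid, drop = FALSE])
    if (fisher_z) {
      Z <- atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12))
      diag(Z) <- 0
      mz <- rowSums(Z) / (ncol(Z) - 1L)
      values[valid] <- tanh(mz)
    } else {
      values[valid] <- (rowSums(C) - 1) / (ncol(C) - 1L)
    }
  }
  structure(list(values = values, voxels = vox, mask = array(as.integer(mask != 0), dm),
                 mask_name = mask_name, n_voxels = length(vox),
                 n_timepoints = Tn, excluded = vox[!valid],
                 fisher_z = fisher_z),
            class = "gbc_map")
}

#' @export
print.gbc_map <- function(x, ...) {
  cat(sprintf("<gbc_map> %s: %d in-mask voxels, %d timepoints\n",
              x$mask_name, x$n_voxels, x$n_timepoints))
  cat(sprintf("  mean GBC %.3f (range %.3f to %.3f)%s\n",
              mean(x$values, na.rm = TRUE), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE),
              if (length(x$excluded)) paste0("; ", length(x$excluded),
                                             " constant voxel(s) excluded") else ""))
  invisible(x)
}

#' Descriptive difference of two GBC maps
#'
#' Voxelwise difference `b - a` over an identical mask, with optional
#' region-level means when community labels are supplied.  Purely
#' descriptive: no inferential statistic is attached.
#'
#' @param map_a,map_b [gbc_map()]s over the same mask (e.g. pre- and
#'   post-treatment).
#' @param community_labels optional integer label per in-mask voxel for
#'   region summaries.
#' @return An object of class `gbc_diff`: list with `difference` (per-voxel
#'   `map_b - map_a`), `mean_difference`, and `region_means` (data.frame,
#'   when labels given).
#' @export
compare_gbc <- function(map_a, map_b, community_labels = NULL) {
  stopifnot(inherits(map_a, "gbc_map"), inherits(map_b, "gbc_map"))
  if (!identical(dim(map_a$mask), dim(map_b$mask)) ||
      !identical(map_a$voxels, map_b$voxels))
    stop("GBC maps were computed on different masks; cannot compare")
  d <- map_b$values - map_a$values
  region_means <- NULL
  if (!is.null(community_labels)) {
    if (length(community_labels) != length(d))
      stop("community_labels length must equal the in-mask voxel count")
    region_means <- do.call(rbind, lapply(sort(unique(community_labels)),
      function(k) data.frame(community = k,
                             mean_a = mean(map_a$values[community_labels == k],
                                           na.rm = TRUE),
                             mean_b = mean(map_b$values[community_labels == k],
                                           na.rm = TRUE),
                             mean_diff = mean(d[community_labels == k],
                                              na.rm = TRUE))))
  }
  structure(list(difference = d, voxels = map_a$voxels,
                 mean_difference = mean(d, na.rm = TRUE),
                 region_means = region_means),
            class = "gbc_diff")
}

#' @export
print.gbc_diff <- function(x, ...) {
  cat(sprintf("<gbc_diff> mean voxelwise difference %.4f over %d voxels\n",
              x$mean_difference, length(x$difference)))
  if (!is.null(x$region_means)) print(round_df(x$region_means, 4))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a GBC map as NIfTI and per-voxel CSV
#'
#' Out-of-mask voxels get `NA` in the NIfTI image; the CSV lists voxel
#' coordinates and values for in-mask voxels.
#'
#' @param map a [gbc_map()].
#' @param nifti_path output NIfTI path (`.nii` / `.nii.gz`); `NULL` to skip.
#' @param csv_path output CSV path; `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_gbc <- function(map, nifti_path = NULL, csv_path = NULL) {
  stopifnot(inherits(map, "gbc_map"))
  if (!is.null(nifti_path)) {
    img <- array(NA_real_, dim(map$mask))
    img[map$voxels] <- map$values
    RNifti::writeNifti(RNifti::asNifti(img), nifti_path)
  }
  if (!is.null(csv_path)) {
    coords <- arrayInd(map$voxels, dim(map$mask))
    utils::write.csv(data.frame(x = coords[, 1], y = coords[, 2],
                                z = coords[, 3], gbc = map$values),
                     csv_path, row.names = FALSE)
  }
  invisible(c(nifti_path, csv_path))
}

#' Write a synthetic 4D volume and its mask as NIfTI (identity affine)
#'
#' @param vol a [simulate_fmri_blocks()] result.
#' @param data_path,mask_path output paths.
#' @return Invisibly, the paths written.
#' @export
write_fmri_nifti <- function(vol, data_path, mask_path) {
  stopifnot(inherits(vol, "synthetic_fmri"))
  RNifti::writeNifti(RNifti::asNifti(vol$data), data_path)
  RNifti::writeNifti(RNifti::asNifti(vol$mask), mask_path)
  invisible(c(data_path, mask_path))
}
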