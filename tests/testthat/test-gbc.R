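test_that("identical time series give GBC of exactly 1", {
  ts <- sin(seq(0, 20, length.out = 50))
  vol <- array(0, c(2, 1, 1, 50))
  vol[1, 1, 1, ] <- ts
  vol[2, 1, 1, ] <- 2 * ts + 3       # linear rescale: still r = 1
  mask <- array(1, c(2, 1, 1))
  m <- gbc_map(vol, mask, min_timepoints = 10)
  expect_equal(m$values, c(1, 1), tolerance = 1e-12)
})

test_that("independent-noise masks have GBC near zero", {
  set.seed(71)
  vol <- array(rnorm(4 * 4 * 1 * 500), c(4, 4, 1, 500))
  m <- gbc_map(vol, array(1, c(4, 4, 1)))
  expect_lt(max(abs(m$values)), 0.05)
})

test_that("two-community GBC matches the block closed form", {
  vol <- simulate_fmri_blocks(c(6, 6, 2), 500, 2, within_r = 0.6,
                              between_r = 0.1, seed = 72)
  m <- gbc_map(vol$data, vol$mask)
  k <- sum(vol$community_labels == 1)
  expected <- (0.6 * (k - 1) + 0.1 * k) / (2 * k - 1)
  for (cl in 1:2) {
    expect_equal(mean(m$values[vol$community_labels == cl]), expected,
                 tolerance = 0.05)
  }
})

test_that("GBC is invariant to per-voxel linear rescaling", {
  vol <- simulate_fmri_blocks(c(3, 3, 1), 200, 2, 0.5, 0.1, seed = 73)
  m1 <- gbc_map(vol$data, vol$mask)
  scaled <- vol$data
  flat <- matrix(scaled, ncol = 200)
  set.seed(74)
  gains <- runif(nrow(flat), 0.5, 5)
  flat <- flat * gains + rnorm(nrow(flat))
  m2 <- gbc_map(array(flat, dim(vol$data)), vol$mask)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("community mean GBC follows the within-correlation rank order", {
  strong <- simulate_fmri_blocks(c(4, 4, 1), 400, 1, 0.7, 0, seed = 75)
  weak <- simulate_fmri_blocks(c(4, 4, 1), 400, 1, 0.2, 0, seed = 76)
  ms <- gbc_map(strong$data, strong$mask)
  mw <- gbc_map(weak$data, weak$mask)
  expect_gt(mean(ms$values), mean(mw$values))
})

test_that("constant voxels are excluded with a record, not propagated", {
  vol <- simulate_fmri_blocks(c(3, 1, 1), 100, 1, 0.5, 0, seed = 77)
  flat <- matrix(vol$data, ncol = 100)
  flat[2, ] <- 7                       # zero-variance voxel
  m <- gbc_map(array(flat, dim(vol$data)), vol$mask)
  expect_true(is.na(m$values[2]))
  expect_equal(m$excluded, 2L)
  expect_false(anyNA(m$values[-2]))
})

test_that("gbc_map validates geometry and length", {
  vol <- array(rnorm(2 * 2 * 2 * 20), c(2, 2, 2, 20))
  expect_error(gbc_map(vol, array(1, c(3, 2, 2))), "extents")
  expect_error(gbc_map(vol, array(0, c(2, 2, 2))), "fewer than 2")
  expect_error(gbc_map(vol, array(1, c(2, 2, 2)), min_timepoints = 100),
               "timepoints")
})

test_that("map differences are zero against self and track a uniform shift", {
  vol <- simulate_fmri_blocks(c(3, 3, 1), 200, 2, 0.5, 0.1, seed = 78)
  m <- gbc_map(vol$data, vol$mask)
  d0 <- compare_gbc(m, m)
  expect_true(all(d0$difference == 0))
  shifted <- m
  shifted$values <- m$values + 0.1
  d1 <- compare_gbc(m, shifted, community_labels = vol$community_labels)
  expect_equal(unique(round(d1$difference, 12)), 0.1)
  expect_equal(d1$region_means$mean_diff, c(0.1, 0.1), tolerance = 1e-12)
})

test_that("raising one community's coherence raises its GBC difference most", {
  pre <- simulate_fmri_blocks(c(6, 6, 1), 400, 2, 0.4, 0.1, seed = 79)
  post <- simulate_fmri_blocks(c(6, 6, 1), 400, 2, 0.7, 0.1, seed = 80)
  # splice: post community 1, pre community 2 -> only community 1 changes
  flat_pre <- matrix(pre$data, ncol = 400)
  flat_post <- matrix(post$data, ncol = 400)
  vox <- which(pre$mask == 1)
  mixed <- flat_pre
  mixed[vox[pre$community_labels == 1], ] <- flat_post[vox[pre$community_labels == 1], ]
  m_pre <- gbc_map(pre$data, pre$mask)
  m_post <- gbc_map(array(mixed, dim(pre$data)), pre$mask)
  d <- compare_gbc(m_pre, m_post, community_labels = pre$community_labels)
  expect_gt(d$region_means$mean_diff[1], d$region_means$mean_diff[2])
})

test_that("maps mismatched in geometry cannot be compared", {
  a <- gbc_map(array(rnorm(2 * 2 * 1 * 50), c(2, 2, 1, 50)), array(1, c(2, 2, 1)))
  b <- gbc_map(array(rnorm(3 * 2 * 1 * 50), c(3, 2, 1, 50)), array(1, c(3, 2, 1)))
  expect_error(compare_gbc(a, b), "different masks")
})

test_that("GBC maps and synthetic volumes round-trip through NIfTI", {
  vol <- simulate_fmri_blocks(c(4, 3, 2), 60, 2, 0.5, 0.1, seed = 81)
  dir <- withr::local_tempdir()
  dpath <- file.path(dir, "vol.nii.gz"); mpath <- file.path(dir, "mask.nii.gz")
  write_fmri_nifti(vol, dpath, mpath)
  m1 <- gbc_map(vol$data, vol$mask)
  m2 <- gbc_map(dpath, mpath)
  expect_equal(m1$values, m2$values, tolerance = 1e-6)
  gpath <- file.path(dir, "gbc.nii.gz")
  write_gbc(m1, nifti_path = gpath, csv_path = file.path(dir, "gbc.csv"))
  img <- as.array(RNifti::readNifti(gpath))
  expect_equal(img[vol$mask == 1], m1$values, tolerance = 1e-6)
  tab <- utils::read.csv(file.path(dir, "gbc.csv"))
  expect_equal(nrow(tab), sum(vol$mask))
})
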