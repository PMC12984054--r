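test_that("lung-window normalisation maps HU by the clip/scale formula", {
  v <- function(hu) apply_window(ct_volume(array(hu, c(1, 1, 1))))$data[1]
  expect_equal(v(-500), 0.5)
  expect_equal(v(250), 1.0)
  expect_equal(v(-1250), 0.0)
  expect_equal(v(-875), 0.25)
  expect_equal(v(10000), 1.0)
  # monotone non-decreasing in HU
  hus <- seq(-2000, 1000, by = 37)
  vals <- vapply(hus, v, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("identity and constant resampling are exact", {
  set.seed(3)
  vol <- ct_volume(array(rnorm(20^3, -500, 100), c(20, 20, 20)))
  rs <- resample_isotropic(vol, c(1, 1, 1))
  expect_lt(max(abs(rs$data - vol$data)), 1e-6)
  const <- ct_volume(array(7, c(12, 10, 8)), spacing = c(2, 1.5, 1))
  rc <- resample_isotropic(const, c(1, 1, 1))
  interior <- rc$data[2:22, 2:13, 2:7]
  expect_lt(max(abs(interior - 7)), 1e-5)
  expect_equal(rc$spacing, c(1, 1, 1))
})

test_that("a linear ramp resamples onto its analytic values", {
  n <- 32
  ramp <- ct_volume(array(rep(seq(0, 2 * (n - 1), by = 2), n * n), c(n, n, n)),
                    spacing = c(2, 2, 2))
  out <- resample_isotropic(ramp, c(1, 1, 1))
  expected <- (seq_len(dim(out$data)[1]) - 1) # slope 1 per mm, origin 0
  rel <- abs(out$data[, 16, 16] - expected) / pmax(abs(expected), 1)
  expect_lt(max(rel[5:(length(rel) - 6)]), 0.01)
})

test_that("mask resampling is order 0 and label-preserving", {
  m <- array(0L, c(10, 10, 10)); m[3:6, 4:7, 2:9] <- 2L
  mask <- region_mask(m, spacing = c(2, 2, 2))
  out <- resample_isotropic(mask, c(1, 1, 1))
  expect_s3_class(out, "region_mask")
  expect_setequal(unique(as.vector(out$data)), c(0L, 2L))
  expect_error(resample_isotropic(mask, c(1, 1, 1), order = 3L), "order 0")
})

test_that("windowing commutes with resampling", {
  set.seed(9)
  base <- array(rnorm(18^3, -600, 150), c(18, 18, 18))
  sm <- smooth_test_field(base)
  vol <- ct_volume(sm, spacing = c(1.6, 1.2, 1))
  a <- apply_window(resample_isotropic(vol, c(1, 1, 1)))
  b <- resample_isotropic(apply_window(vol), c(1, 1, 1), fill = 0)
  core <- function(x) x$data[4:24, 4:18, 4:15]
  expect_lt(max(abs(core(a) - core(b))), 5e-3)
  # order-0: exact commutation
  mask_like <- ct_volume(array(round(runif(10^3)) * 500 - 800, c(10, 10, 10)),
                         spacing = c(2, 2, 2))
  a0 <- apply_window(resample_isotropic(mask_like, c(1, 1, 1), order = 0L))
  b0 <- resample_isotropic(apply_window(mask_like), c(1, 1, 1), order = 0L, fill = 0)
  expect_lt(max(abs(a0$data - b0$data)), 1e-3)
})

test_that("mask volume is conserved under resampling for ellipsoids", {
  d <- c(24, 24, 18)
  sp <- c(1, 1, 1.4)
  co <- arrayInd(seq_len(prod(d)), d)
  ctr <- (d + 1) / 2
  rho <- ((co[, 1] - ctr[1]) * sp[1] / 4.5)^2 + ((co[, 2] - ctr[2]) * sp[2] / 3.8)^2 +
    ((co[, 3] - ctr[3]) * sp[3] / 3.2)^2
  m <- array(0L, d); m[rho <= 1] <- 1L
  mask <- region_mask(m, spacing = sp)
  vol_in <- sum(mask$data) * prod(sp)
  out <- resample_isotropic(mask, c(1, 1, 1))
  vol_out <- sum(out$data) * 1
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.15)
})

test_that("permuted or flipped NIfTI orientations are normalised on read", {
  td <- withr::local_tempdir()
  m <- array(0L, c(10, 12, 14)); m[3:6, 4:9, 5:11] <- 1L
  mask <- region_mask(m, spacing = c(1, 1.5, 2), origin = c(5, 6, 7))
  # axis-permuted storage: voxel axes run along world (y, z, x)
  img <- RNifti::asNifti(aperm(m, c(2, 3, 1)))
  RNifti::pixdim(img) <- c(1.5, 2, 1)
  aff <- matrix(0, 4, 4); aff[4, 4] <- 1
  aff[2, 1] <- 1.5; aff[3, 2] <- 2; aff[1, 3] <- 1; aff[1:3, 4] <- c(5, 6, 7)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  f <- file.path(td, "perm.nii.gz")
  RNifti::writeNifti(img, f)
  back <- read_nifti_volume(f, mask = TRUE)
  expect_identical(back$data, mask$data)
  expect_equal(back$spacing, mask$spacing, tolerance = 1e-5)
  expect_equal(back$origin, mask$origin, tolerance = 1e-4)
  # flipped first axis, origin at the flipped end
  img2 <- RNifti::asNifti(m[10:1, , ])
  RNifti::pixdim(img2) <- c(1, 1.5, 2)
  aff2 <- diag(c(-1, 1.5, 2, 1)); aff2[1:3, 4] <- c(5 + 9, 6, 7)
  RNifti::qform(img2) <- structure(aff2, code = 2L)
  RNifti::sform(img2) <- structure(aff2, code = 2L)
  f2 <- file.path(td, "flip.nii.gz")
  RNifti::writeNifti(img2, f2)
  back2 <- read_nifti_volume(f2, mask = TRUE)
  expect_identical(back2$data, mask$data)
  expect_equal(back2$origin, mask$origin, tolerance = 1e-4)
})

test_that("load_case validates alignment and content", {
  td <- withr::local_tempdir()
  coh <- phantom_fixture(n = 2, seed = 301)
  p <- coh[[1]]
  write_nifti_volume(p$ct, file.path(td, "ct.nii.gz"))
  write_nifti_volume(p$tumor_mask, file.path(td, "tumor.nii.gz"))
  case <- load_case(file.path(td, "ct.nii.gz"), file.path(td, "tumor.nii.gz"))
  expect_equal(sum(case$tumor$data), sum(p$tumor_mask$data))
  # empty mask is an explicit error
  empty <- region_mask(array(0L, dim(p$ct$data)))
  write_nifti_volume(empty, file.path(td, "empty.nii.gz"))
  expect_error(load_case(file.path(td, "ct.nii.gz"), file.path(td, "empty.nii.gz")),
               "empty ROI")
  # >5 mm origin discrepancy is an error
  shifted <- region_mask(p$tumor_mask$data, origin = c(10, 0, 0))
  write_nifti_volume(shifted, file.path(td, "shift.nii.gz"))
  expect_error(load_case(file.path(td, "ct.nii.gz"), file.path(td, "shift.nii.gz")),
               "origin")
  # mild grid mismatch: resampled with a warning, voxel count preserved
  half <- resample_isotropic(p$tumor_mask, c(2, 2, 2))
  write_nifti_volume(half, file.path(td, "half.nii.gz"))
  expect_warning(case2 <- load_case(file.path(td, "ct.nii.gz"),
                                    file.path(td, "half.nii.gz")),
                 "resampled")
  expect_gt(sum(case2$tumor$data), 0)
})
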