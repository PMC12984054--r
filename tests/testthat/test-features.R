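test_that("a digital ball has near-unit sphericity and isotropic axes", {
  s <- array(0L, c(24, 24, 24))
  co <- arrayInd(seq_len(length(s)), dim(s))
  s[sqrt(rowSums((co - 12.5)^2)) <= 8] <- 1L
  f <- shape_features(region_mask(s))
  expect_gte(f[["sphericity"]], 0.95)
  expect_lte(f[["sphericity"]], 1.0)
  expect_lt(abs(f[["elongation"]] - 1), 0.05)
  expect_lt(abs(f[["flatness"]] - 1), 0.05)
  expect_lt(abs(f[["surface_area"]] - 4 * pi * 64) / (4 * pi * 64), 0.05)
  expect_equal(f[["voxel_volume"]], sum(s))
  expect_lt(abs(f[["max_3d_diameter"]] - 16) / 16, 0.1)
})

test_that("constant-intensity regions have degenerate texture", {
  arr <- array(0.5, c(8, 8, 8))
  m <- array(0L, c(8, 8, 8)); m[2:7, 2:7, 2:7] <- 1L
  f <- extract_region_features(ct_volume(arr), region_mask(m))
  expect_equal(f[["firstorder_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_joint_energy"]], 1)
  expect_equal(f[["firstorder_uniformity"]], 1)
})

test_that("first-order features match direct arithmetic", {
  f <- firstorder_features(1:9)
  expect_equal(f[["mean"]], 5)
  expect_equal(f[["variance"]], 20 / 3)
  expect_equal(f[["median"]], 5)
  expect_equal(f[["energy"]], sum((1:9)^2))
  # agreement with the masked voxel list on a phantom tumor, to 1e-10
  coh <- phantom_fixture(n = 2, seed = 301)
  p <- coh[[1]]
  w <- apply_window(p$ct)
  vals <- w$data[p$tumor_mask$data > 0L]
  f2 <- extract_region_features(w, p$tumor_mask)
  expect_equal(f2[["firstorder_mean"]], mean(vals), tolerance = 1e-10)
  expect_equal(f2[["firstorder_variance"]],
               mean((vals - mean(vals))^2), tolerance = 1e-10)
})

test_that("features are invariant to axis permutation and intensity scaling", {
  coh <- phantom_fixture(n = 2, seed = 301)
  p <- coh[[1]]
  w <- apply_window(p$ct)
  f0 <- extract_region_features(w, p$tumor_mask)
  perm <- c(3, 1, 2)
  wp <- ct_volume(aperm(w$data, perm), w$spacing[perm])
  mp <- region_mask(aperm(p$tumor_mask$data, perm), w$spacing[perm])
  fp <- extract_region_features(wp, mp)
  fo <- grep("^firstorder", names(f0))
  expect_equal(f0[fo], fp[fo], tolerance = 1e-6)
  tex <- grep("^(glcm|glrlm|glszm)", names(f0))
  expect_equal(f0[tex], fp[tex], tolerance = 1e-3)
  # doubling intensities leaves shape features unchanged exactly
  f2 <- extract_region_features(ct_volume(w$data / 2), p$tumor_mask)
  sh <- grep("^shape", names(f0))
  expect_identical(f0[sh], f2[sh])
})

test_that("extract_all builds the expected block structure", {
  coh <- phantom_fixture(n = 2, seed = 301)
  fms <- lapply(coh, function(p) local_feature_map(apply_window(p$ct), p$tumor_mask))
  hms <- lapply(seq_along(fms), function(i) cluster_habitats(fms[[i]], 3, seed = i))
  tab <- suppressWarnings(extract_all(coh, c(1, 3, 5), hms))
  # 7 blocks (intra, peri1, peri3, peri5, hab1..3) x 88 features + PatientID
  expect_equal(ncol(tab), 7 * 88 + 1)
  expect_equal(nrow(tab), 2)
  expect_setequal(attr(tab, "regions"),
                  c("intra", "peri1", "peri3", "peri5", "hab1", "hab2", "hab3"))
  # restricting regions restricts columns
  tab2 <- suppressWarnings(extract_all(coh, 3, hms, regions = c("peri3", "hab")))
  expect_equal(ncol(tab2), 4 * 88 + 1)
  # shuffling patients shuffles rows only
  tabr <- suppressWarnings(extract_all(rev(coh), c(1, 3, 5), rev(hms)))
  expect_equal(unname(as.matrix(tabr[2, -1])), unname(as.matrix(tab[1, -1])))
  # a patient without imaging is flagged, not dropped
  broken <- coh
  broken[[2]]$ct <- NULL
  tabf <- suppressWarnings(extract_all(broken, 3, regions = "peri3"))
  expect_equal(nrow(tabf), 2L)
  expect_identical(attr(tabf, "flagged"), broken[[2]]$id)
  expect_true(all(is.na(as.numeric(tabf[2, -1]))))
})

test_that("an absent habitat subregion yields 88 missing cells", {
  coh <- phantom_fixture(n = 2, seed = 301)
  fms <- lapply(coh, function(p) local_feature_map(apply_window(p$ct), p$tumor_mask))
  hms <- lapply(seq_along(fms), function(i) cluster_habitats(fms[[i]], 3, seed = i))
  # erase subregion 2 in patient 1
  hms[[1]]$labels$data[hms[[1]]$labels$data == 2L] <- 1L
  tab <- suppressWarnings(extract_all(coh, 3, hms, regions = c("hab")))
  na1 <- is.na(as.numeric(tab[1, -1]))
  expect_equal(sum(na1), 88L)
  expect_true(all(grepl("^hab2_", colnames(tab)[-1][na1])))
})

test_that("KNN imputation respects the training split", {
  tab <- data.frame(a = c(1, 1, 1, 5, 5), b = c(2, 2, 2, 9, 9),
                    c = c(3, NA, 3, 7, 7))
  out <- knn_impute(tab, k_neighbors = 2)
  # nearest rows by (a, b) are rows 1 and 3, both with c = 3
  expect_equal(out$c[2], 3)
  # table with no missing values returns unchanged
  expect_identical(knn_impute(out), out)
  # fully-missing training column is an explicit error
  tab2 <- data.frame(a = 1:4, b = c(NA, NA, 7, 8))
  expect_error(knn_impute(tab2, split = c("train", "train", "val", "val")),
               "b")
  # planted missingness on a phantom-like table: imputation error below IQR
  set.seed(8)
  n <- 60
  base <- matrix(rnorm(n * 6), n, 6) %*% matrix(runif(36, -1, 1), 6, 6)
  colnames(base) <- paste0("f", 1:6)
  holed <- as.data.frame(base)
  idx <- cbind(sample(n, 12), sample(2:4, 12, replace = TRUE))
  truth <- base[idx]
  holed[idx] <- NA
  filled <- knn_impute(holed)
  err <- abs(as.matrix(filled)[idx] - truth)
  expect_lt(median(err), median(apply(base, 2, IQR)))
})
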