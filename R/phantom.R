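#' Configuration for the phantom CT cohort generator
#'
#' Defines the study conditions the generator emulates: small solid
#' ellipsoidal tumors (maximum CT diameter at most 2 cm) embedded in
#' lung-density parenchyma, with `k_true` planted texture subregions arranged
#' as angular sectors around the tumor centre (wavy planar boundaries,
#' random widths and orientation), a peritumoral shell whose texture
#' variance carries label information, an optional chest-wall slab on one
#' volume face, and a logistic label-generating model tying STAS status to
#' mediastinal-window tumor size, the planted fraction of the last
#' subregion, and a latent peritumoral texture score (all standardised
#' across the cohort before the coefficients apply).
#'
#' Sector (rather than concentric-shell) subregions are used because every
#' subregion then owns bulk interior volume much wider than the 5-voxel
#' moving window of [local_feature_map()]; shells thinner than the window
#' would be smoothed into a radial continuum and no clustering method could
#' recover them at these tumor sizes.
#'
#' @param n_patients number of patients (>= 2).
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param voxel_spacing_mm length-3 voxel spacing, mm.
#' @param volume_shape length-3 voxel counts of each CT volume.
#' @param parenchyma_hu c(mean, sd) of lung parenchyma HU.
#' @param tumor_hu_by_subregion list of length `k_true`; each element
#'   c(mean HU, sd HU, texture correlation length in voxels), ordered core
#'   to rim.
#' @param k_true number of planted subregions (>= 1).
#' @param diameter_range_mm c(min, max) maximum tumor diameter, mm; the upper
#'   bound may not exceed 20 mm. The default lower bound of 10 mm keeps every
#'   planted shell at least ~1.7 voxels thick at 1 mm spacing so the three
#'   default subregions stay resolvable.
#' @param stas_coefficients named vector: `intercept`, `mwts` (standardised
#'   mediastinal-window size), `frac_sub3` (standardised planted volume
#'   fraction of the highest-index subregion, subregion 3 at the default
#'   `k_true`), `peri` (standardised peritumoral texture score). The
#'   defaults are calibrated (by direct simulation of the label model) so
#'   that the true covariates carry single-variable AUCs of about 0.65
#'   (size), 0.87 (habitat fraction) and 0.81 (peritumoral score) at ~38%
#'   STAS prevalence — the signal strengths reported for the clinical,
#'   habitat and 3 mm peritumoral models in dual-centre STAS cohorts of
#'   small solid adenocarcinomas.
#' @param peri_frac_correlation correlation between the latent peritumoral
#'   texture score and the (standardised) subregion-3 fraction: one tumor
#'   biology drives both intratumoral composition and peritumoral spread.
#' @param peritumoral_noise c(sd, gain): extra HU noise in the 3 mm
#'   peritumoral shell has standard deviation `sd * exp(gain * score)` where
#'   `score` is the patient's latent peritumoral texture score.
#' @param chest_wall logical; paint a +40 +/- 10 HU slab on the high-x face
#'   (excluded from the lung mask) to exercise ring exclusion.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(n_patients = 40,
                           seed = 1L,
                           voxel_spacing_mm = c(1, 1, 1),
                           volume_shape = c(64, 64, 64),
                           parenchyma_hu = c(mean = -800, sd = 30),
                           tumor_hu_by_subregion = list(c(60, 15, 1),
                                                        c(10, 25, 2),
                                                        c(-80, 40, 3)),
                           k_true = length(tumor_hu_by_subregion),
                           diameter_range_mm = c(10, 20),
                           stas_coefficients = c(intercept = -1.15,
                                                 mwts = 1.2,
                                                 frac_sub3 = 2.2,
                                                 peri = 1.3),
                           peri_frac_correlation = 0.5,
                           peritumoral_noise = c(sd = 25, gain = 0.5),
                           chest_wall = TRUE) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (k_true < 1) stop("k_true must be >= 1")
  if (length(tumor_hu_by_subregion) != k_true)
    stop("tumor_hu_by_subregion must have one (mean, sd, corr-length) triple per subregion")
  sds <- c(parenchyma_hu[2], vapply(tumor_hu_by_subregion, `[`, 0, 2))
  if (any(sds < 0)) stop("all sd values must be >= 0")
  if (diameter_range_mm[2] > 20)
    stop("maximum tumor diameter may not exceed 20 mm (small solid tumors only)")
  if (diameter_range_mm[1] <= 4 || diameter_range_mm[1] >= diameter_range_mm[2])
    stop("diameter_range_mm must be an increasing pair within (4, 20]")
  req <- c("intercept", "mwts", "frac_sub3", "peri")
  if (!all(req %in% names(stas_coefficients)))
    stop("stas_coefficients must name intercept, mwts, frac_sub3, peri")
  if (any(volume_shape < 8)) stop("volume_shape axes must be >= 8 voxels")
  if (abs(peri_frac_correlation) > 1)
    stop("peri_frac_correlation must lie in [-1, 1]")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 volume_shape = as.integer(volume_shape),
                 parenchyma_hu = as.numeric(parenchyma_hu),
                 tumor_hu_by_subregion = tumor_hu_by_subregion,
                 k_true = as.integer(k_true),
                 diameter_range_mm = as.numeric(diameter_range_mm),
                 stas_coefficients = stas_coefficients,
                 peri_frac_correlation = as.numeric(peri_frac_correlation),
                 peritumoral_noise = as.numeric(peritumoral_noise),
                 chest_wall = isTRUE(chest_wall)),
            class = "phantom_config")
}

expit <- function(x) 1 / (1 + exp(-x))

zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Gaussian smoothing of a small 3-D array, mirror-free normalised kernel
conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

smooth_field <- function(arr, sigma) {
  for (ax in 1:3) arr <- apply_along(arr, conv_matrix(dim(arr)[ax], sigma), ax)
  arr
}

# unit-variance smoothed Gaussian texture field
texture_field <- function(dims, corr_len) {
  f <- smooth_field(array(stats::rnorm(prod(dims)), dim = dims), corr_len)
  s <- stats::sd(f)
  if (s == 0) f else f / s
}

#' Generate a phantom cohort
#'
#' Deterministic given `config$seed`: patient-level parameters, clinical
#' covariates and STAS labels are drawn first from the cohort seed, then each
#' patient's voxel grid is rendered from a per-patient seed derived from it,
#' so labels do not depend on rendering and `render = FALSE` yields the same
#' clinical table and labels without the (comparatively expensive) volumes.
#'
#' @param config a [phantom_config()].
#' @param render logical; render CT volumes and masks (default `TRUE`).
#' @return A list of `phantom_patient` objects, each with elements `id`,
#'   `ct`, `tumor_mask`, `lung_mask`, `true_subregion_labels` (values
#'   1..k_true on tumor voxels), `clinical` (one-row data frame), `stas`
#'   (0/1), and `truth` (planted quantities: diameter, subregion volume
#'   fractions, peritumoral texture score).
#' @export
generate_cohort <- function(config, render = TRUE) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  sp <- config$voxel_spacing_mm
  shape <- config$volume_shape
  n <- config$n_patients
  k <- config$k_true

  # capacity check: the narrowest admissible sector must still be a few
  # voxels wide at the equator of the smallest admissible tumor
  min_semi_vox <- 0.7 * config$diameter_range_mm[1] / 2 / max(sp)
  if (k > floor(pi * min_semi_vox / 2))
    stop(sprintf(paste("k_true = %d exceeds the distinguishable subregion",
                       "capacity of tumors as small as %g mm"),
                 k, config$diameter_range_mm[1]))

  set.seed(config$seed)
  dr <- config$diameter_range_mm
  diam <- stats::runif(n, dr[1], dr[2])
  ratio_b <- stats::runif(n, 0.7, 1)
  ratio_c <- stats::runif(n, 0.7, 1)
  jitter <- matrix(stats::runif(3 * n, -6, 6), n, 3)
  # per-patient sector widths (volume fractions) with a floor so no sector
  # degenerates, plus a random rotation of the whole sector fan
  widths <- t(vapply(seq_len(n), function(i) {
    f <- 0.5 + stats::runif(k, 0, 1)
    f / sum(f)
  }, numeric(k)))
  rotation <- stats::runif(n, 0, 2 * pi)
  perturb_amp <- stats::runif(n, 0.03, 0.10)
  perturb_phase <- stats::runif(n, 0, 2 * pi)
  rho <- config$peri_frac_correlation
  peri_score <- rho * zstd(widths[, k]) +
    sqrt(1 - rho^2) * stats::rnorm(n)
  mwts_frac <- stats::runif(n, 0.6, 0.95)

  clinical <- data.frame(
    PatientID = sprintf("P%03d", seq_len(n)),
    Age = round(stats::rnorm(n, 62.8, 8.1), 1),
    Lwts = round(diam + stats::rnorm(n, 0, 0.5), 1),
    Mwts = round(diam * mwts_frac + stats::rnorm(n, 0, 0.5), 1),
    Sex = ifelse(stats::runif(n) < 0.48, "Male", "Female"),
    Smoking_history = ifelse(stats::runif(n) < 0.28, "Yes", "No"),
    CEA = ifelse(stats::runif(n) < 0.17, ">5.0", "<=5.0"),
    SCCA = ifelse(stats::runif(n) < 0.02, ">1.5", "<=1.5"),
    NSE = ifelse(stats::runif(n) < 0.34, ">17.0", "<=17.0"),
    CYFRA = ifelse(stats::runif(n) < 0.20, ">3.3", "<=3.3"),
    Location = sample(c("RUL", "RML", "RLL", "LUL", "LLL"), n, replace = TRUE,
                      prob = c(0.33, 0.07, 0.20, 0.20, 0.20)),
    Lobulation = ifelse(stats::runif(n) < 0.90, "Present", "Absent"),
    Spiculation = ifelse(stats::runif(n) < 0.32, "Present", "Absent"),
    Bronchial_cutoff = ifelse(stats::runif(n) < 0.16, "Present", "Absent"),
    Air_bronchogram = ifelse(stats::runif(n) < 0.40, "Present", "Absent"),
    Vacuole = ifelse(stats::runif(n) < 0.30, "Present", "Absent"),
    stringsAsFactors = FALSE)

  frac_sub3 <- widths[, k]
  b <- config$stas_coefficients
  lp <- b[["intercept"]] + b[["mwts"]] * zstd(clinical$Mwts) +
    b[["frac_sub3"]] * zstd(frac_sub3) + b[["peri"]] * zstd(peri_score)
  stas <- as.integer(stats::runif(n) < expit(lp))
  clinical$STAS <- stas

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    p <- list(id = clinical$PatientID[i], stas = stas[i],
              clinical = clinical[i, , drop = FALSE],
              truth = list(diameter_mm = diam[i], frac_sub3 = frac_sub3[i],
                           peri_score = peri_score[i],
                           sector_fractions = widths[i, ]))
    if (render) {
      rseed <- (config$seed %% 100000L) * 20000L + i
      p <- c(p, render_phantom(config, rseed, diam[i],
                               c(1, ratio_b[i], ratio_c[i]) * diam[i] / 2,
                               jitter[i, ], widths[i, ], rotation[i],
                               perturb_amp[i], perturb_phase[i],
                               peri_score[i]))
    }
    class(p) <- "phantom_patient"
    patients[[i]] <- p
  }
  attr(patients, "config") <- config
  patients
}

# render one patient's CT, tumor/lung masks, and true subregion labels
render_phantom <- function(config, rseed, diam, semi_mm, jitter, widths,
                           rotation, amp, phase, peri_score) {
  set.seed(rseed)
  sp <- config$voxel_spacing_mm
  shape <- config$volume_shape
  k <- config$k_true
  ph <- config$parenchyma_hu

  vol <- array(stats::rnorm(prod(shape), ph[1], ph[2]), dim = shape)
  lung <- array(1L, dim = shape)
  if (config$chest_wall) {
    xs <- (shape[1] - 5L):shape[1]
    vol[xs, , ] <- stats::rnorm(length(xs) * shape[2] * shape[3], 40, 10)
    lung[xs, , ] <- 0L
  }

  # tumor centre in voxel index units (0-based), kept clear of the slab
  ctr <- (shape - 1) / 2 + jitter
  hi_lim <- shape[1] - 8 - semi_mm[1] / sp[1]
  ctr[1] <- min(ctr[1], hi_lim)

  half_vox <- ceiling(semi_mm / sp) + 1L
  lo <- pmax(floor(ctr) - half_vox, 0)
  hi <- pmin(ceiling(ctr) + half_vox, shape - 1)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- (ix - ctr[1]) * sp[1]; gy <- (iy - ctr[2]) * sp[2]; gz <- (iz - ctr[3]) * sp[3]
  X <- array(gx, dim = c(length(ix), length(iy), length(iz)))
  Y <- aperm(array(gy, dim = c(length(iy), length(ix), length(iz))), c(2, 1, 3))
  Z <- aperm(array(gz, dim = c(length(iz), length(ix), length(iy))), c(2, 3, 1))
  rho <- sqrt((X / semi_mm[1])^2 + (Y / semi_mm[2])^2 + (Z / semi_mm[3])^2)
  inside <- rho <= 1

  # angular sectors around the x axis, boundaries gently wavy in radius
  az <- (atan2(Z, Y) + rotation + amp * sin(2 * pi * rho + phase)) %% (2 * pi)
  lab_box <- array(0L, dim = dim(rho))
  if (k > 1) {
    cuts <- 2 * pi * cumsum(widths)[seq_len(k - 1)]
    lab_box[inside] <- findInterval(az[inside], cuts) + 1L
  } else lab_box[inside] <- 1L

  box <- vol[ix + 1, iy + 1, iz + 1, drop = FALSE]
  for (j in seq_len(k)) {
    spec <- config$tumor_hu_by_subregion[[j]]
    sel <- lab_box == j
    if (!any(sel)) next
    f <- spec[1] + spec[2] * texture_field(dim(box), spec[3])
    box[sel] <- f[sel]
  }
  vol[ix + 1, iy + 1, iz + 1] <- box

  tumor <- array(0L, dim = shape)
  tbox <- array(0L, dim = dim(rho)); tbox[inside] <- 1L
  tumor[ix + 1, iy + 1, iz + 1] <- tbox
  labels <- array(0L, dim = shape)
  labels[ix + 1, iy + 1, iz + 1] <- lab_box

  tumor_mask <- region_mask(tumor, sp)
  lung_mask <- region_mask(lung, sp)
  # peritumoral shell texture carries the latent score
  shell <- dilate_mask(tumor_mask, 3)$data > 0L & tumor == 0L & lung == 1L
  ns <- sum(shell)
  pn <- config$peritumoral_noise
  vol[shell] <- vol[shell] + stats::rnorm(ns, 0, pn[1] * exp(pn[2] * peri_score))

  list(ct = ct_volume(vol, sp),
       tumor_mask = tumor_mask,
       lung_mask = lung_mask,
       true_subregion_labels = region_mask(labels, sp))
}

#' @export
print.phantom_patient <- function(x, ...) {
  cat(sprintf("<phantom_patient %s> STAS=%d, diameter %.1f mm, subregion-3 fraction %.2f%s\n",
              x$id, x$stas, x$truth$diameter_mm, x$truth$frac_sub3,
              if (is.null(x$ct)) " (not rendered)" else ""))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' One NIfTI file per volume/mask (CT, tumor, lung, true subregion labels),
#' one clinical CSV, and a JSON manifest listing patient IDs, file paths,
#' cohort split (if assigned) and the generating seed.
#'
#' @param patients output of [generate_cohort()] (rendered).
#' @param directory output directory (created if needed).
#' @param overwrite logical; refuse to clobber an existing manifest unless
#'   `TRUE`.
#' @param split optional character vector (train/val/test) per patient.
#' @return The manifest path, invisibly.
#' @export
cohort_to_disk <- function(patients, directory, overwrite = FALSE, split = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest.json already exists in the target directory (use overwrite = TRUE)")
  if (is.null(split)) split <- rep(NA_character_, length(patients))
  entries <- vector("list", length(patients))
  clin <- do.call(rbind, lapply(patients, `[[`, "clinical"))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    if (is.null(p$ct)) stop(sprintf("patient %s was generated without rendering", p$id))
    files <- c(ct = sprintf("%s_ct.nii.gz", p$id),
               tumor = sprintf("%s_tumor.nii.gz", p$id),
               lung = sprintf("%s_lung.nii.gz", p$id),
               habitat_true = sprintf("%s_habitat_true.nii.gz", p$id))
    write_nifti_volume(p$ct, file.path(directory, files["ct"]))
    write_nifti_volume(p$tumor_mask, file.path(directory, files["tumor"]))
    write_nifti_volume(p$lung_mask, file.path(directory, files["lung"]))
    write_nifti_volume(p$true_subregion_labels, file.path(directory, files["habitat_true"]))
    entries[[i]] <- list(id = p$id, files = as.list(files), split = split[i],
                         stas = p$stas)
  }
  utils::write.csv(clin, file.path(directory, "clinical.csv"), row.names = FALSE)
  cfg <- attr(patients, "config")
  manifest <- list(seed = if (!is.null(cfg)) cfg$seed else NA,
                   n_patients = length(patients),
                   clinical = "clinical.csv",
                   patients = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a phantom cohort written by [cohort_to_disk()]
#'
#' @param directory directory containing `manifest.json`.
#' @return A list of `phantom_patient`-like objects (without `truth`).
#' @export
read_cohort <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(manifest_path)
  clin <- utils::read.csv(file.path(directory, manifest$clinical),
                          stringsAsFactors = FALSE)
  lapply(manifest$patients, function(e) {
    paths <- file.path(directory, unlist(e$files))
    names(paths) <- names(e$files)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("missing file for patient %s: %s", e$id,
                   paste(basename(missing), collapse = ", ")))
    case <- load_case(paths["ct"], paths["tumor"], paths["lung"])
    structure(list(id = e$id, ct = case$ct, tumor_mask = case$tumor,
                   lung_mask = case$lung,
                   true_subregion_labels = read_nifti_volume(paths["habitat_true"], mask = TRUE),
                   clinical = clin[clin$PatientID == e$id, , drop = FALSE],
                   stas = e$stas, split = e$split),
              class = "phantom_patient")
  })
}
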