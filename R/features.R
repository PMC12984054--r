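#' Extract the full radiomic feature vector of one region
#'
#' 88 features on the original image: 14 shape, 18 first-order, 24 GLCM
#' (symmetric, distance 1, averaged over the 13 unique 3-D directions),
#' 16 GLRLM and 16 GLSZM, with fixed-bin-count discretisation of the
#' windowed intensities. Names are prefixed by feature class
#' (`shape_`, `firstorder_`, `glcm_`, `glrlm_`, `glszm_`).
#'
#' A region with fewer than 2 voxels yields an all-missing vector with a
#' warning (downstream KNN imputation fills it); a single-slice region gets
#' the 2-D shape fallback of [shape_features()].
#'
#' @param ct a windowed [ct_volume()].
#' @param region an aligned [region_mask()] (any nonzero label is foreground).
#' @param bins discretisation bins (>= 8; default 32).
#' @return Named numeric vector of length 88.
#' @export
extract_region_features <- function(ct, region, bins = 32L) {
  assert_aligned(ct, region, "CT and region mask")
  if (bins < 8) stop("at least 8 discretisation bins are required")
  nvox <- sum(region$data > 0L)
  template <- feature_names_88()
  if (nvox < 2) {
    warning("region has fewer than 2 voxels; returning all-missing features")
    return(stats::setNames(rep(NA_real_, length(template)), template))
  }
  bin_region <- region_mask(array(as.integer(region$data > 0L), dim = dim(region$data)),
                            region$spacing, region$origin)
  sf <- shape_features(bin_region)
  values <- ct$data[region$data > 0L]
  fo <- firstorder_features(values, prod(ct$spacing), bins)
  ga <- gray_array(ct, bin_region, bins)
  gl <- glcm_features(ga); rl <- glrlm_features(ga); sz <- glszm_features(ga)
  out <- c(stats::setNames(as.numeric(sf), paste0("shape_", names(sf))),
           stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(gl, paste0("glcm_", names(gl))),
           stats::setNames(rl, paste0("glrlm_", names(rl))),
           stats::setNames(sz, paste0("glszm_", names(sz))))
  stopifnot(identical(names(out), template))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_names_88 <- function() {
  shape <- c("mesh_volume", "voxel_volume", "surface_area", "surface_volume_ratio",
             "sphericity", "max_3d_diameter", "max_2d_diameter_slice",
             "max_2d_diameter_column", "max_2d_diameter_row", "major_axis_length",
             "minor_axis_length", "least_axis_length", "elongation", "flatness")
  fo <- c("energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
          "mean", "median", "iqr", "range", "mad", "rmad", "rms", "skewness",
          "kurtosis", "variance", "uniformity")
  glcm <- c("autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
            "cluster_tendency", "contrast", "correlation", "difference_average",
            "difference_entropy", "difference_variance", "joint_energy",
            "joint_entropy", "imc1", "imc2", "idm", "idmn", "id", "idn",
            "inverse_variance", "max_probability", "sum_average", "sum_entropy",
            "sum_squares", "mcc")
  glrlm <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
             "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")
  glszm <- c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv", "ze",
             "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle")
  c(paste0("shape_", shape), paste0("firstorder_", fo), paste0("glcm_", glcm),
    paste0("glrlm_", glrlm), paste0("glszm_", glszm))
}

#' Extract features for every patient and region into a feature table
#'
#' One row per patient; one 88-column block per region. Standard regions are
#' the intratumoral mask (`intra`), the 1/3/5 mm peritumoral rings (`peri1`,
#' `peri3`, `peri5`) and, when habitat maps are supplied, one block per
#' habitat subregion (`hab1`..`habk`). A habitat subregion absent in a
#' patient produces 88 missing cells in that row (imputed later); a patient
#' missing a required mask is flagged in the `flagged` attribute, not
#' dropped.
#'
#' @param cohort list of patients (each with `ct`, `tumor_mask`, `lung_mask`,
#'   `id`), e.g. from [generate_cohort()].
#' @param ring_distances numeric vector of peritumoral distances in mm.
#' @param habitat_maps optional list of [cluster_habitats()] results aligned
#'   with `cohort`.
#' @param window a [window_spec()] applied to each CT before extraction.
#' @param bins discretisation bins.
#' @param regions optional character subset of region tags to extract (e.g.
#'   `c("peri3", "hab")`); `"hab"` selects all habitat blocks.
#' @return A data frame with `PatientID` and prefixed feature columns;
#'   attribute `regions` lists the block tags.
#' @export
extract_all <- function(cohort, ring_distances = c(1, 3, 5), habitat_maps = NULL,
                        window = window_spec(), bins = 32L, regions = NULL) {
  k <- if (!is.null(habitat_maps)) max(vapply(habitat_maps, `[[`, 0L, "k")) else 0L
  if (!is.null(habitat_maps) &&
      length(unique(vapply(habitat_maps, `[[`, 0L, "k"))) > 1L)
    stop("habitat maps must share a single k across patients")
  tags <- c("intra", paste0("peri", ring_distances), if (k > 0) paste0("hab", seq_len(k)))
  if (!is.null(regions)) {
    want <- unique(unlist(lapply(regions, function(r)
      if (r == "hab") grep("^hab", tags, value = TRUE) else r)))
    tags <- intersect(tags, want)
  }
  rows <- vector("list", length(cohort))
  flagged <- character(0)
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    if (is.null(p$ct) || is.null(p$tumor_mask)) {
      flagged <- c(flagged, p$id)
      rows[[i]] <- stats::setNames(
        rep(NA_real_, 88L * length(tags)),
        unlist(lapply(tags, function(t) paste0(t, "_", feature_names_88()))))
      next
    }
    w <- apply_window(p$ct, window)
    feats <- list()
    for (tag in tags) {
      reg <- if (tag == "intra") {
        p$tumor_mask
      } else if (grepl("^peri", tag)) {
        dmm <- as.numeric(sub("^peri", "", tag))
        tryCatch(peritumoral_ring(p$tumor_mask, dmm, p$lung_mask),
                 error = function(e) NULL)
      } else {
        j <- as.integer(sub("^hab", "", tag))
        hm <- habitat_maps[[i]]
        sel <- array(as.integer(hm$labels$data == j), dim = dim(hm$labels$data))
        region_mask(sel, p$tumor_mask$spacing, p$tumor_mask$origin)
      }
      fv <- if (is.null(reg) || sum(reg$data > 0L) < 2L) {
        if (!is.null(reg)) warning(sprintf("patient %s region %s has < 2 voxels", p$id, tag))
        stats::setNames(rep(NA_real_, 88L), feature_names_88())
      } else {
        suppressWarnings(extract_region_features(w, reg, bins))
      }
      feats[[tag]] <- stats::setNames(fv, paste0(tag, "_", names(fv)))
    }
    rows[[i]] <- unlist(feats, use.names = TRUE)
    names(rows[[i]]) <- sub("^[^.]*\\.", "", names(rows[[i]]))
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(PatientID = vapply(cohort, `[[`, "", "id"), tab,
               stringsAsFactors = FALSE)
  attr(tab, "regions") <- tags
  attr(tab, "flagged") <- flagged
  tab
}

#' KNN imputation of missing feature cells
#'
#' Missing cells are filled with the mean of the `k_neighbors` nearest
#' training rows under Euclidean distance on the Z-scored complete columns
#' (columns observed everywhere). The scaler and the neighbour pool come
#' from the training split only; validation/test rows are imputed against
#' training rows, never against each other.
#'
#' @param table data frame of numeric feature columns (non-numeric columns
#'   such as IDs are carried through untouched).
#' @param split character vector per row, `"train"` marking training rows;
#'   `NULL` treats every row as training.
#' @param k_neighbors number of neighbours (default 5).
#' @return The table with no missing numeric cells.
#' @export
knn_impute <- function(table, split = NULL, k_neighbors = 5L) {
  num <- vapply(table, is.numeric, TRUE)
  X <- as.matrix(table[, num, drop = FALSE])
  if (!anyNA(X)) return(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  tr <- split == "train"
  fully_missing <- colnames(X)[colSums(!is.na(X[tr, , drop = FALSE])) == 0]
  if (length(fully_missing))
    stop("columns with no observed training value: ",
         paste(fully_missing, collapse = ", "))
  complete_cols <- colSums(is.na(X)) == 0
  if (!any(complete_cols))
    stop("KNN imputation needs at least one fully observed column")
  mu <- colMeans(X[tr, complete_cols, drop = FALSE])
  sdv <- apply(X[tr, complete_cols, drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X[, complete_cols, drop = FALSE], 2, mu), 2, sdv, "/")
  Ztr <- Z[tr, , drop = FALSE]
  tr_idx <- which(tr)
  for (i in which(rowSums(is.na(X)) > 0)) {
    d2 <- colSums((t(Ztr) - Z[i, ])^2)
    if (tr[i]) d2[tr_idx == i] <- Inf       # a row never imputes itself
    miss <- which(is.na(X[i, ]))
    for (j in miss) {
      obs <- !is.na(X[tr_idx, j])
      cand <- order(d2 + ifelse(obs, 0, Inf))[seq_len(min(k_neighbors, sum(obs)))]
      X[i, j] <- mean(X[tr_idx[cand], j])
    }
  }
  table[, num] <- X
  table
}
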