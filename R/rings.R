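#' Spacing-aware Euclidean dilation of a binary mask
#'
#' A voxel belongs to the dilated set iff the Euclidean distance (in mm,
#' honouring anisotropic spacing) between its centre and the centre of some
#' foreground voxel is at most `distance_mm`. This is exact set semantics:
#' the result equals a brute-force pairwise voxel-centre distance check.
#'
#' @param tumor a binary [region_mask()].
#' @param distance_mm dilation distance in mm (> 0; a distance smaller than
#'   the closest neighbour spacing returns the input set).
#' @return A binary `region_mask` containing the input.
#' @export
dilate_mask <- function(tumor, distance_mm) {
  if (!inherits(tumor, "region_mask")) stop("tumor must be a region_mask")
  if (!is.finite(distance_mm) || distance_mm <= 0) stop("distance must be > 0")
  fg <- tumor$data > 0L
  if (!any(fg)) stop("empty mask: nothing to dilate")
  sp <- tumor$spacing
  d <- dim(fg)

  # integer offsets whose physical length is within the distance
  r <- floor(distance_mm / sp)
  og <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (og$dx * sp[1])^2 + (og$dy * sp[2])^2 + (og$dz * sp[3])^2 <= distance_mm^2
  og <- og[keep, , drop = FALSE]

  # work inside the padded bounding box of the foreground
  co <- which(fg, arr.ind = TRUE)
  lo <- pmax(apply(co, 2, min) - (r + 1L), 1L)
  hi <- pmin(apply(co, 2, max) + (r + 1L), d)
  box <- fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  db <- dim(box)
  acc <- box
  for (i in seq_len(nrow(og))) {
    o <- c(og$dx[i], og$dy[i], og$dz[i])
    if (all(o == 0L)) next
    dst <- src <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      dst[[ax]] <- max(1L, 1L + o[ax]):min(db[ax], db[ax] + o[ax])
      src[[ax]] <- dst[[ax]] - o[ax]
      if (length(dst[[ax]]) < 1L || dst[[ax]][1] > dst[[ax]][length(dst[[ax]])]) ok <- FALSE
    }
    if (!ok) next
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] | box[src[[1]], src[[2]], src[[3]]]
  }
  out <- array(FALSE, dim = d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- acc
  region_mask(array(as.integer(out), dim = d), sp, tumor$origin)
}

#' Peritumoral ring at a fixed distance from the tumor boundary
#'
#' The ring is the dilated tumor minus the tumor itself, intersected with an
#' optional exclusion mask (typically the lung mask, so that chest wall and
#' mediastinum never contribute peritumoral voxels). Every ring voxel centre
#' lies within `(0, distance_mm]` mm of the tumor voxel-centre set.
#'
#' @param tumor binary [region_mask()].
#' @param distance_mm ring thickness in mm (1, 3 or 5 in the standard
#'   analysis).
#' @param exclude_mask optional aligned binary `region_mask`; the ring is
#'   intersected with its foreground.
#' @return A binary `region_mask`, disjoint from the tumor.
#' @export
peritumoral_ring <- function(tumor, distance_mm, exclude_mask = NULL) {
  dil <- dilate_mask(tumor, distance_mm)
  ring <- dil$data > 0L & !(tumor$data > 0L)
  if (!is.null(exclude_mask)) {
    assert_aligned(tumor, exclude_mask, "tumor and exclusion masks")
    ring <- ring & exclude_mask$data > 0L
  }
  if (!any(ring))
    stop(sprintf("ring vanished: no voxels remain at %g mm after exclusion", distance_mm))
  region_mask(array(as.integer(ring), dim = dim(tumor$data)),
              tumor$spacing, tumor$origin)
}

#' Heuristic lung mask from HU
#'
#' Simple reproducible stand-in for manual chest-wall correction: voxels
#' below `threshold_hu` (default -300 HU) are lung-like. Intended for real
#' data without a provided lung mask; phantom cohorts carry an exact one.
#'
#' @param ct a [ct_volume()] in HU.
#' @param threshold_hu upper HU bound for lung parenchyma.
#' @return A binary `region_mask`.
#' @export
lung_mask_from_hu <- function(ct, threshold_hu = -300) {
  region_mask(array(as.integer(ct$data < threshold_hu), dim = dim(ct$data)),
              ct$spacing, ct$origin)
}
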