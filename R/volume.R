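#' CT volume container
#'
#' A minimal container for a 3-D CT intensity grid in Hounsfield units,
#' together with its voxel spacing and world origin. Voxel indices are
#' 0-based in world computations; world coordinate of voxel (i,j,k) is
#' `origin + c(i,j,k) * spacing`. All distances are millimetres.
#'
#' @param data 3-D numeric array of intensities (HU, or `[0,1]` after
#'   windowing).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3 world position of voxel (0,0,0), mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  if (any(!is.finite(data)))
    stop("intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Region mask container
#'
#' Integer label grid aligned to a [ct_volume()]. Label 0 is background;
#' binary masks use 1 for foreground, habitat maps use 1..k.
#'
#' @param data 3-D array of non-negative integer labels.
#' @param spacing,origin as in [ct_volume()].
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  storage.mode(data) <- "integer"
  if (any(is.na(data)) || any(data < 0L))
    stop("mask labels must be non-negative integers")
  v <- ct_volume(array(0, dim = dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "region_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s voxels, spacing %s mm, %d foreground, labels {%s}\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$data > 0L),
              paste(sort(unique(x$data[x$data > 0L])), collapse = ",")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_aligned <- function(a, b, what = "grids") {
  if (!same_grid(a, b)) stop(sprintf("%s are not aligned (shape/spacing/origin mismatch)", what))
  invisible(TRUE)
}

#' Write a volume or mask to NIfTI
#'
#' @param x a `ct_volume` or `region_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  # encode origin in the sform translation column
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume or mask
#'
#' Axis-permuted or axis-flipped storage orientations (affines with one
#' nonzero entry per row/column) are reoriented to the package convention of
#' ascending world coordinates along array axes; oblique affines are not
#' supported and raise an error.
#'
#' @param path NIfTI file.
#' @param mask logical; read as integer `region_mask` rather than `ct_volume`.
#' @return A `ct_volume` or `region_mask`.
#' @export
read_nifti_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  aff <- RNifti::xform(img)
  a3 <- aff[1:3, 1:3]
  # world axis addressed by each voxel axis
  world_of <- apply(abs(a3), 2, which.max)
  off_diag_ok <- TRUE
  for (j in 1:3) for (i in 1:3)
    if (i != world_of[j] && abs(a3[i, j]) > 1e-4 * max(abs(a3)))
      off_diag_ok <- FALSE
  if (anyDuplicated(world_of) || !off_diag_ok)
    stop("oblique NIfTI orientations are not supported")
  org <- as.numeric(aff[1:3, 4])
  sp <- vapply(1:3, function(j) abs(a3[world_of[j], j]), 0)
  # flip axes stored in descending world order, fixing the origin
  for (j in 1:3) {
    if (a3[world_of[j], j] < 0) {
      idx <- rev(seq_len(dim(arr)[j]))
      arr <- switch(j, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      org[world_of[j]] <- org[world_of[j]] + (dim(arr)[j] - 1) * a3[world_of[j], j]
    }
  }
  # permute so array axis i runs along world axis i
  p <- match(1:3, world_of)
  arr <- aperm(arr, p)
  sp <- sp[p]
  if (mask) region_mask(array(as.integer(round(arr)), dim = dim(arr)), sp, org)
  else ct_volume(arr, sp, org)
}

mask_indices <- function(mask) which(mask$data > 0L)

#' Voxel coordinates (0-based) of foreground voxels
#' @noRd
mask_coords <- function(mask) {
  idx <- which(mask$data > 0L)
  arrayInd(idx, dim(mask$data)) - 1L
}
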