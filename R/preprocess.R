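#' Lung-window specification
#'
#' Display-window normalisation maps the HU interval
#' `[level - width/2, level + width/2]` linearly onto `[0, 1]`, clipping
#' outside. Defaults are the standard lung window (width 1500 HU, level
#' -500 HU), so `[-1250, 250]` HU maps onto the unit interval.
#'
#' @param width window width in HU (> 0).
#' @param level window level (centre) in HU.
#' @return A `window_spec` object.
#' @export
window_spec <- function(width = 1500, level = -500) {
  if (!is.finite(width) || width <= 0) stop("window width must be > 0")
  structure(list(width = width, level = level), class = "window_spec")
}

#' Apply window width/level normalisation
#'
#' @param volume a [ct_volume()] in HU.
#' @param spec a [window_spec()].
#' @return A `ct_volume` with intensities in `[0, 1]`.
#' @export
apply_window <- function(volume, spec = window_spec()) {
  lo <- spec$level - spec$width / 2
  out <- pmin(pmax((volume$data - lo) / spec$width, 0), 1)
  ct_volume(array(out, dim = dim(volume$data)), volume$spacing, volume$origin)
}

## -- cubic B-spline machinery (separable, mirror boundaries) ----------------

# Convert samples to cubic B-spline coefficients along dim 1 of a matrix.
# Causal/anti-causal recursive filter with pole sqrt(3) - 2.
bspline_prefilter <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(m)
  z <- sqrt(3) - 2
  cp <- m * 6
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z))))
  zk <- z^(seq_len(horizon) - 1)
  out <- cp
  out[1L, ] <- as.vector(zk %*% cp[seq_len(horizon), , drop = FALSE])
  for (i in 2:n) out[i, ] <- cp[i, ] + z * out[i - 1L, ]
  out[n, ] <- (z / (z * z - 1)) * (out[n, ] + z * out[n - 1L, ])
  for (i in (n - 1L):1L) out[i, ] <- z * (out[i + 1L, ] - out[i, ])
  out
}

# Cubic B-spline basis evaluated at |t| <= 2
bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 2 / 3 - at^2 + at^3 / 2,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

mirror_index <- function(i, n) {
  # reflect 0-based index i into [0, n-1] (half-sample-free mirror)
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- i %% p
  i[i < 0] <- i[i < 0] + p
  ifelse(i >= n, p - i, i)
}

# Interpolation weight matrix mapping n_in samples (unit-spaced, 0-based) to
# values at positions `t` (0-based input index units). order 0 = nearest,
# order 3 = interpolating cubic B-spline (prefilter applied by caller flag).
interp_matrix <- function(t, n_in, order) {
  n_out <- length(t)
  w <- matrix(0, n_out, n_in)
  if (order == 0L) {
    idx <- mirror_index(as.integer(round(t)), n_in)
    w[cbind(seq_len(n_out), idx + 1L)] <- 1
  } else {
    base <- floor(t)
    for (off in -1:2) {
      k <- mirror_index(as.integer(base) + off, n_in)
      w[cbind(seq_len(n_out), k + 1L)] <-
        w[cbind(seq_len(n_out), k + 1L)] + bspline3(t - (base + off))
    }
  }
  w
}

apply_along <- function(arr, w, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- w %*% matrix(a, nrow = da[1])
  out <- array(m, dim = c(nrow(w), da[2], da[3]))
  aperm(out, order(perm))
}

#' Resample a volume or mask to a target voxel spacing
#'
#' Intensity volumes are resampled with an interpolating cubic B-spline
#' (recursive prefilter, then separable cubic basis evaluation); masks use
#' order-0 (nearest-neighbour) interpolation so only input labels appear in
#' the output. The output grid shares the input origin; its extent matches
#' the input extent to within one voxel. Positions falling outside the input
#' field of view take `fill` (default -1024 HU, air) for intensities and 0
#' for masks.
#'
#' @param volume a [ct_volume()] or [region_mask()].
#' @param target_spacing numeric length-3, mm (default isotropic 1 mm).
#' @param order 0 (nearest, required for masks) or 3 (cubic B-spline).
#' @param fill out-of-field fill value for intensity volumes.
#' @return Object of the same class as `volume` at the new spacing.
#' @export
resample_isotropic <- function(volume, target_spacing = c(1, 1, 1),
                               order = if (inherits(volume, "region_mask")) 0L else 3L,
                               fill = -1024) {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  if (!order %in% c(0L, 3L)) stop("interpolation order must be 0 or 3")
  is_mask <- inherits(volume, "region_mask")
  if (is_mask && order != 0L) stop("masks must be resampled with order 0")
  d_in <- dim(volume$data)
  d_out <- pmax(1L, as.integer(round(d_in * volume$spacing / target_spacing)))
  if (any(d_out < 1L)) stop("target spacing collapses an axis to zero length")

  arr <- volume$data
  storage.mode(arr) <- "double"
  outside <- vector("list", 3L)
  for (ax in 1:3) {
    t <- (seq_len(d_out[ax]) - 1) * target_spacing[ax] / volume$spacing[ax]
    outside[[ax]] <- t < -0.5 | t > d_in[ax] - 0.5
    if (order == 3L && d_in[ax] >= 2L) {
      perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
      a <- aperm(arr, perm)
      da <- dim(a)
      a <- array(bspline_prefilter(matrix(a, nrow = da[1])), dim = da)
      arr <- aperm(a, order(perm))
    }
    arr <- apply_along(arr, interp_matrix(t, dim(arr)[ax], order), ax)
  }
  oob <- array(FALSE, dim = d_out)
  if (any(outside[[1]])) oob[outside[[1]], , ] <- TRUE
  if (any(outside[[2]])) oob[, outside[[2]], ] <- TRUE
  if (any(outside[[3]])) oob[, , outside[[3]]] <- TRUE

  if (is_mask) {
    arr[oob] <- 0
    region_mask(array(as.integer(round(arr)), dim = d_out),
                target_spacing, volume$origin)
  } else {
    arr[oob] <- fill
    ct_volume(arr, target_spacing, volume$origin)
  }
}

# nearest-neighbour resample of a mask onto the grid of a reference volume,
# honouring both origins
resample_mask_to_grid <- function(mask, ref) {
  d_out <- dim(ref$data)
  out <- array(0L, dim = d_out)
  idx <- vector("list", 3L)
  ok <- vector("list", 3L)
  for (ax in 1:3) {
    world <- ref$origin[ax] + (seq_len(d_out[ax]) - 1) * ref$spacing[ax]
    t <- (world - mask$origin[ax]) / mask$spacing[ax]
    i <- as.integer(round(t))
    ok[[ax]] <- i >= 0L & i < dim(mask$data)[ax]
    idx[[ax]] <- pmin(pmax(i, 0L), dim(mask$data)[ax] - 1L) + 1L
  }
  sub <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sub[!ok[[1]], , ] <- 0L
  sub[, !ok[[2]], ] <- 0L
  sub[, , !ok[[3]]] <- 0L
  region_mask(sub, ref$spacing, ref$origin)
}

#' Load a CT case (volume + tumor mask, optional lung mask)
#'
#' Reads NIfTI files and verifies grid alignment. A mask whose grid disagrees
#' with the CT (but whose origin is within 5 mm) is resampled onto the CT
#' grid with nearest-neighbour interpolation and a warning; a larger origin
#' discrepancy is an error. An empty tumor mask is an error.
#'
#' @param ct_path,tumor_path,lung_path NIfTI file paths (`lung_path` optional).
#' @return A list with elements `ct`, `tumor`, and `lung` (`NULL` if absent).
#' @export
load_case <- function(ct_path, tumor_path, lung_path = NULL) {
  ct <- read_nifti_volume(ct_path)
  fix <- function(m, what) {
    if (same_grid(m, ct)) return(m)
    if (any(abs(m$origin - ct$origin) > 5))
      stop(sprintf("%s origin differs from CT by more than 5 mm", what))
    warning(sprintf("%s grid differs from CT; resampled with nearest-neighbour", what))
    resample_mask_to_grid(m, ct)
  }
  tumor <- fix(read_nifti_volume(tumor_path, mask = TRUE), "tumor mask")
  if (sum(tumor$data > 0L) == 0L) stop("empty ROI: tumor mask has no foreground voxels")
  lung <- if (!is.null(lung_path)) fix(read_nifti_volume(lung_path, mask = TRUE), "lung mask")
  list(ct = ct, tumor = tumor, lung = lung)
}
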