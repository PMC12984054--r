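#' Per-voxel local feature map inside the tumor
#'
#' For every tumor voxel, 19 first-order statistics of the moving window
#' centred on it (window clipped at volume borders, never padded): mean,
#' median, minimum, maximum, range, variance, standard deviation, skewness,
#' kurtosis, energy (sum of squares), root mean square, entropy (32 fixed
#' bins on `[0,1]`), uniformity, mean absolute deviation, robust mean
#' absolute deviation (values within the P10-P90 band), and percentiles
#' 10/25/75/90.
#'
#' With `mask_windows = TRUE` (the default) window statistics are computed
#' from the window voxels that lie inside the tumor mask, so habitat
#' structure reflects intratumoral texture rather than the attenuation jump
#' to adjacent lung parenchyma; set it to `FALSE` to include every in-volume
#' window voxel.
#'
#' @param ct a windowed [ct_volume()] with intensities in `[0, 1]`.
#' @param tumor aligned binary [region_mask()].
#' @param window odd window edge length in voxels (>= 3, default 5).
#' @param mask_windows logical; restrict windows to tumor voxels (default
#'   `TRUE`).
#' @return A `voxel_feature_map`: list with `features` (n_voxel x 19 matrix),
#'   `index` (linear voxel indices), `intensity` (centre-voxel windowed
#'   value), `dim`, and `window`.
#' @export
local_feature_map <- function(ct, tumor, window = 5L, mask_windows = TRUE) {
  assert_aligned(ct, tumor, "CT and tumor mask")
  if (window < 3L || window %% 2L == 0L) stop("window must be an odd integer >= 3")
  d <- dim(ct$data)
  if (any(window > d)) stop("window larger than the volume")
  if (min(ct$data) < -1e-6 || max(ct$data) > 1 + 1e-6)
    stop("expected a windowed volume with intensities in [0,1]")
  idx <- which(tumor$data > 0L)
  if (!length(idx)) stop("empty ROI: tumor mask has no foreground voxels")
  co <- arrayInd(idx, d)
  h <- (window - 1L) / 2L
  off <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  off_lin <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  n <- length(idx)
  V <- matrix(NA_real_, n, nrow(off))
  interior <- all(apply(co, 2, min) > h) && all(apply(co, 2, max) <= d - h)
  for (j in seq_len(nrow(off))) {
    if (interior) {
      lin <- idx + off_lin[j]
      if (mask_windows) {
        ok <- tumor$data[lin] > 0L
        V[ok, j] <- ct$data[lin[ok]]
      } else V[, j] <- ct$data[lin]
      next
    }
    p1 <- co[, 1] + off[j, 1]; p2 <- co[, 2] + off[j, 2]; p3 <- co[, 3] + off[j, 3]
    ok <- p1 >= 1L & p1 <= d[1] & p2 >= 1L & p2 <= d[2] & p3 >= 1L & p3 <= d[3]
    lin <- p1 + (p2 - 1L) * d[1] + (p3 - 1L) * d[1] * d[2]
    if (mask_windows) ok[ok] <- tumor$data[lin[ok]] > 0L
    V[ok, j] <- ct$data[lin[ok]]
  }
  cnt <- rowSums(!is.na(V))
  mu <- rowMeans(V, na.rm = TRUE)
  C <- V - mu
  m2 <- rowMeans(C^2, na.rm = TRUE)
  m3 <- rowMeans(C^3, na.rm = TRUE)
  m4 <- rowMeans(C^4, na.rm = TRUE)
  # one radix sort of the whole matrix gives all row order statistics
  # (NAs sort last; cnt tracks each row's valid length)
  S <- matrix(V[order(row(V), V)], nrow = n, byrow = TRUE)
  row_q <- function(prob) {             # type-7 quantile from sorted rows
    h <- (cnt - 1) * prob + 1
    lo <- floor(h); hi <- ceiling(h)
    S[cbind(seq_len(n), lo)] * (1 - (h - lo)) + S[cbind(seq_len(n), hi)] * (h - lo)
  }
  qs <- cbind(row_q(.1), row_q(.25), row_q(.5), row_q(.75), row_q(.9))
  vmin <- S[, 1]
  vmax <- S[cbind(seq_len(n), cnt)]
  energy <- rowSums(V^2, na.rm = TRUE)
  # fixed 32 bins on [0,1]
  B <- pmin(floor(V * 32) + 1L, 32L)
  keys <- seq_len(n) + n * (B - 1L)
  counts <- matrix(tabulate(keys[!is.na(keys)], n * 32L), n, 32L)
  Pb <- counts / cnt
  lp <- Pb * log2(Pb)
  lp[counts == 0L] <- 0
  ent <- -rowSums(lp)
  unif <- rowSums(Pb^2)
  W <- V
  W[V < qs[, 1] | V > qs[, 5]] <- NA
  rmad <- rowMeans(abs(W - rowMeans(W, na.rm = TRUE)), na.rm = TRUE)
  rmad[is.na(rmad)] <- 0
  feats <- cbind(
    mean = mu, median = qs[, 3], min = vmin, max = vmax, range = vmax - vmin,
    variance = m2, sd = sqrt(m2),
    skewness = ifelse(m2 > 0, m3 / m2^1.5, 0),
    kurtosis = ifelse(m2 > 0, m4 / m2^2, 0),
    energy = energy, rms = sqrt(energy / cnt),
    entropy = ent, uniformity = unif,
    mad = rowMeans(abs(C), na.rm = TRUE), rmad = rmad,
    p10 = qs[, 1], p25 = qs[, 2], p75 = qs[, 4], p90 = qs[, 5])
  stopifnot(ncol(feats) == 19L)
  structure(list(features = feats, index = idx,
                 intensity = ct$data[idx], dim = d, window = window,
                 spacing = ct$spacing, origin = ct$origin),
            class = "voxel_feature_map")
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion scaled by degrees of
#' freedom: `CH = [B/(k-1)] / [W/(n-k)]` with `B` the weighted squared
#' distance of cluster centroids to the grand centroid and `W` the pooled
#' within-cluster squared distance.
#'
#' @param points numeric matrix (observations x features).
#' @param labels integer cluster assignment, >= 2 nonempty clusters.
#' @return The CH score (`Inf` with a warning when `W = 0`).
#' @export
ch_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(points)
  if (k < 2) stop("ch_index requires at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("all clusters must be nonempty")
  grand <- colMeans(points)
  B <- 0; W <- 0
  for (j in seq_len(k)) {
    Pj <- points[labels == j, , drop = FALSE]
    cj <- colMeans(Pj)
    B <- B + nrow(Pj) * sum((cj - grand)^2)
    W <- W + sum(sweep(Pj, 2, cj)^2)
  }
  if (W <= 0) {
    warning("zero within-cluster dispersion; CH index is infinite")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

# z-score columns, dropping zero-variance ones
zscore_matrix <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) return(NULL)
  sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
}

# k-means++ seeding
kmeanspp_centers <- function(X, k, n2 = rowSums(X^2)) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- pmax(n2 - 2 * as.numeric(X %*% centers[1, ]) + sum(centers[1, ]^2), 0)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) stop("fewer distinct feature rows than clusters")
    i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, pmax(n2 - 2 * as.numeric(X %*% centers[j, ]) + sum(centers[j, ]^2), 0))
  }
  centers
}

run_kmeans <- function(Z, k, seed, restarts = 10L) {
  set.seed(seed)
  if (nrow(unique(Z)) < k) stop("fewer distinct feature rows than clusters")
  n2 <- rowSums(Z^2)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_centers(Z, k, n2)
    fit <- suppressWarnings(stats::kmeans(Z, centers = init, iter.max = 50L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster tumor voxels into habitat subregions
#'
#' K-means (k-means++ seeding, 10 restarts, fixed seed) on the within-sample
#' Z-scored 19-feature voxel map. Clusters are relabelled in increasing order
#' of mean windowed intensity, so label 1 is always the darkest habitat; this
#' imposes a deterministic cross-patient correspondence.
#'
#' @param fm a [local_feature_map()] result.
#' @param k number of subregions (>= 2).
#' @param seed RNG seed for seeding/restarts.
#' @return A `habitat_map`: list with `labels` ([region_mask()] valued 1..k
#'   on tumor voxels), `k`, `fractions` (per-label voxel fractions summing to
#'   1), and `assignment` (per-voxel labels).
#' @export
cluster_habitats <- function(fm, k, seed = 1L) {
  if (!inherits(fm, "voxel_feature_map")) stop("fm must be a voxel_feature_map")
  if (k < 2) stop("k must be >= 2 (a single habitat is not a partition)")
  if (k > nrow(fm$features)) stop("k exceeds the number of tumor voxels")
  Z <- zscore_matrix(fm$features)
  if (is.null(Z)) stop("fewer distinct feature rows than clusters")
  fit <- run_kmeans(Z, k, seed)
  raw <- fit$cluster
  mean_int <- vapply(seq_len(k), function(j) mean(fm$intensity[raw == j]), 0)
  relabel <- match(seq_len(k), order(mean_int))
  lab <- relabel[raw]
  arr <- array(0L, dim = fm$dim)
  arr[fm$index] <- lab
  fractions <- tabulate(lab, k) / length(lab)
  structure(list(labels = region_mask(arr, fm$spacing, fm$origin), k = as.integer(k),
                 fractions = fractions, assignment = lab,
                 zfeatures = Z),
            class = "habitat_map")
}

#' Select the cohort-wide habitat count by mean Calinski-Harabasz index
#'
#' For each candidate k, every sample is clustered with [cluster_habitats()]
#' and its CH index computed on the Z-scored voxel features; per-sample
#' scores are averaged and the k with the highest mean is selected,
#' cohort-wide (per-sample k values are deliberately not allowed). Samples
#' failing to cluster at some k are skipped with a warning; a k succeeding
#' on fewer than half the samples is excluded.
#'
#' @param fms list of [local_feature_map()] results (>= 5 samples).
#' @param k_grid integer candidates (default 2..8).
#' @param seed RNG seed.
#' @return A `k_selection` list: `k_grid`, `ch_scores` (mean per k),
#'   `k_star`, and the per-sample score matrix.
#' @export
select_k <- function(fms, k_grid = 2:8, seed = 1L) {
  if (length(fms) < 5) stop("select_k requires at least 5 samples")
  scores <- matrix(NA_real_, length(fms), length(k_grid),
                   dimnames = list(NULL, paste0("k", k_grid)))
  for (s in seq_along(fms)) {
    for (j in seq_along(k_grid)) {
      res <- tryCatch({
        hm <- cluster_habitats(fms[[s]], k_grid[j], seed = seed + s)
        ch_index(hm$zfeatures, hm$assignment)
      }, error = function(e) {
        warning(sprintf("sample %d failed at k = %d: %s", s, k_grid[j],
                        conditionMessage(e)))
        NA_real_
      })
      scores[s, j] <- res
    }
  }
  ok <- colMeans(!is.na(scores)) >= 0.5
  if (!any(ok)) stop("no k succeeded on at least half the samples")
  mean_ch <- colMeans(scores, na.rm = TRUE)
  mean_ch[!ok] <- NA_real_
  k_star <- k_grid[which.max(mean_ch)]
  structure(list(k_grid = k_grid, ch_scores = mean_ch, k_star = k_star,
                 per_sample = scores),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> mean CH by k:\n")
  print(round(x$ch_scores, 2))
  cat("selected k* =", x$k_star, "\n")
  invisible(x)
}
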