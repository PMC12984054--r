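# First-order and texture (GLCM / GLRLM / GLSZM) feature definitions.
#
# Texture features use fixed-bin-count discretisation (default 32 bins over
# the region's intensity range), a symmetric co-occurrence matrix at distance
# 1 averaged over the 13 unique 3-D directions, run-length matrices averaged
# the same way, and size-zone matrices over 26-connected iso-intensity zones.

# the 13 unique direction offsets of the 26-neighbourhood (one per +/- pair)
DIRECTIONS_13 <- {
  og <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  og <- og[!(og[, 1] == 0 & og[, 2] == 0 & og[, 3] == 0), ]
  keep <- og[, 3] > 0 | (og[, 3] == 0 & (og[, 2] > 0 | (og[, 2] == 0 & og[, 1] > 0)))
  og[keep, , drop = FALSE]
}

#' First-order intensity features of a region
#'
#' 18 statistics of the masked voxel intensities: energy, total energy
#' (energy times voxel volume), entropy and uniformity on the discretised
#' intensities, minimum, 10th/90th percentiles, maximum, mean, median,
#' interquartile range, range, mean absolute deviation, robust mean absolute
#' deviation (P10-P90 band), root mean square, skewness, kurtosis
#' (non-excess), and population variance.
#'
#' @param values numeric vector of masked voxel intensities.
#' @param voxel_volume volume of one voxel in mm^3.
#' @param bins number of discretisation bins for entropy/uniformity.
#' @return Named numeric vector of length 18.
#' @export
firstorder_features <- function(values, voxel_volume = 1, bins = 32L) {
  n <- length(values)
  mu <- mean(values)
  cx <- values - mu
  m2 <- mean(cx^2); m3 <- mean(cx^3); m4 <- mean(cx^4)
  q <- stats::quantile(values, c(.10, .25, .50, .75, .90), names = FALSE)
  g <- discretise(values, bins)
  p <- tabulate(g, bins) / n
  p <- p[p > 0]
  band <- values[values >= q[1] & values <= q[5]]
  c(energy = sum(values^2),
    total_energy = voxel_volume * sum(values^2),
    entropy = -sum(p * log2(p)),
    minimum = min(values),
    p10 = q[1], p90 = q[5],
    maximum = max(values),
    mean = mu,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(values) - min(values),
    mad = mean(abs(cx)),
    rmad = if (length(band)) mean(abs(band - mean(band))) else 0,
    rms = sqrt(mean(values^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

# fixed-bin-count discretisation to integers 1..bins
discretise <- function(values, bins = 32L) {
  rng <- range(values)
  if (rng[2] <= rng[1]) return(rep(1L, length(values)))
  pmin(as.integer(floor((values - rng[1]) / (rng[2] - rng[1]) * bins)) + 1L, bins)
}

# cropped integer gray-level array (0 outside region) + region voxel count
gray_array <- function(ct, region, bins) {
  idx <- which(region$data > 0L)
  g <- discretise(ct$data[idx], bins)
  co <- arrayInd(idx, dim(region$data))
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, dim(region$data))
  G <- array(0L, dim = hi - lo + 1L)
  G[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- g
  list(G = G, np = length(idx), levels = sort(unique(g)))
}

shift_pairs <- function(G, o) {
  d <- dim(G)
  sx <- max(1L, 1L + o[1]):min(d[1], d[1] + o[1])
  sy <- max(1L, 1L + o[2]):min(d[2], d[2] + o[2])
  sz <- max(1L, 1L + o[3]):min(d[3], d[3] + o[3])
  a <- G[sx, sy, sz, drop = FALSE]
  b <- G[sx - o[1], sy - o[2], sz - o[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  cbind(a[ok], b[ok])
}

glcm_from_pairs <- function(pairs, nbin) {
  C <- matrix(0, nbin, nbin)
  if (nrow(pairs)) {
    tb <- tabulate(pairs[, 1] + nbin * (pairs[, 2] - 1L), nbin * nbin)
    C <- matrix(tb, nbin, nbin)
  }
  C + t(C)
}

glcm_features_one <- function(P, levels) {
  # restrict to present levels; level values (bin indices) stay meaningful
  P <- P[levels, levels, drop = FALSE]
  s <- sum(P)
  if (s <= 0) return(NULL)
  p <- P / s
  ng <- length(levels)
  iv <- as.numeric(levels)
  I <- matrix(iv, ng, ng); J <- t(I)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  # sum / difference distributions
  ksum <- as.integer(outer(iv, iv, "+")); kdif <- abs(as.integer(outer(iv, iv, "-")))
  pv <- as.numeric(p)
  ps <- rowsum(pv, ksum); psum <- as.numeric(ps); ks <- as.integer(rownames(ps))
  pd <- rowsum(pv, kdif); pdif <- as.numeric(pd); kd <- as.integer(rownames(pd))
  da <- sum(kd * pdif)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  hxy <- ent(pv)
  pxy <- as.numeric(outer(px, py))
  hxy1 <- -sum(pv[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px); hy <- ent(py)
  mcc <- if (ng < 2) 1 else {
    A <- p / pmax(px, .Machine$double.eps)
    B <- sweep(p, 2, pmax(py, .Machine$double.eps), "/")
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  mu <- mux
  c(autocorrelation = sum(I * J * p),
    joint_average = mux,
    cluster_prominence = sum((I + J - 2 * mu)^4 * p),
    cluster_shade = sum((I + J - 2 * mu)^3 * p),
    cluster_tendency = sum((I + J - 2 * mu)^2 * p),
    contrast = sum((I - J)^2 * p),
    correlation = if (sx > 0 && sy > 0) (sum(I * J * p) - mux * muy) / (sx * sy) else 1,
    difference_average = da,
    difference_entropy = ent(pdif),
    difference_variance = sum((kd - da)^2 * pdif),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idm = sum(p / (1 + (I - J)^2)),
    idmn = sum(p / (1 + ((I - J) / ng)^2)),
    id = sum(p / (1 + abs(I - J))),
    idn = sum(p / (1 + abs(I - J) / ng)),
    inverse_variance = sum(p[I != J] / (I - J)[I != J]^2),
    max_probability = max(p),
    sum_average = sum(ks * psum),
    sum_entropy = ent(psum),
    sum_squares = sum((I - mu)^2 * p),
    mcc = mcc)
}

glcm_features <- function(ga) {
  nbin <- max(ga$levels)
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    f <- glcm_features_one(glcm_from_pairs(shift_pairs(ga$G, DIRECTIONS_13[r, ]), nbin),
                           ga$levels)
    if (is.null(f)) next
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {
    # no co-occurring pairs in any direction (scattered single voxels)
    nm <- names(glcm_features_one(matrix(c(0, 1, 1, 0), 2), c(1L, 2L)))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  acc / nd
}

# run-length matrix features, averaged over 13 directions
glrlm_features <- function(ga) {
  G <- ga$G
  idx <- which(G > 0L)
  co <- arrayInd(idx, dim(G))
  g <- G[idx]
  np <- ga$np
  acc <- NULL
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    o <- DIRECTIONS_13[r, ]
    ax <- which(o != 0)[1]
    t <- co[, ax] * o[ax]
    start <- co - outer(t, o)
    key <- (start[, 1] + 2L) + (start[, 2] + 2L) * 1000L + (start[, 3] + 2L) * 1000000L
    ord <- order(key, t)
    kk <- key[ord]; tt <- t[ord]; gg <- g[ord]
    newrun <- c(TRUE, kk[-1] != kk[-length(kk)] | tt[-1] != tt[-length(tt)] + 1L |
                  gg[-1] != gg[-length(gg)])
    rid <- cumsum(newrun)
    len <- tabulate(rid)
    gray <- gg[newrun]
    f <- rl_stats(gray, len, np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(DIRECTIONS_13)
}

rl_stats <- function(gray, len, np, prefix = c("sre", "lre", "gln", "glnn", "rln",
                                               "rlnn", "rp", "glv", "rv", "re",
                                               "lglre", "hglre", "srlgle", "srhgle",
                                               "lrlgle", "lrhgle")) {
  nr <- length(gray)
  p <- rep(1, nr) / nr
  sum_g2 <- sum(tabulate(gray)^2)
  sum_l2 <- sum(tabulate(len)^2)
  mug <- sum(gray) / nr; mul <- sum(len) / nr
  out <- c(mean(1 / len^2), mean(len^2),
           sum_g2 / nr, sum_g2 / nr^2,
           sum_l2 / nr, sum_l2 / nr^2,
           nr / np,
           mean((gray - mug)^2), mean((len - mul)^2),
           -sum(p * log2(p)),
           mean(1 / gray^2), mean(gray^2),
           mean(1 / (gray^2 * len^2)), mean(gray^2 / len^2),
           mean(len^2 / gray^2), mean(gray^2 * len^2))
  names(out) <- prefix
  out
}

# 26-connected iso-intensity zones via vectorised label propagation
glszm_features <- function(ga) {
  G <- ga$G
  idx <- which(G > 0L)
  n <- length(idx)
  co <- arrayInd(idx, dim(G))
  g <- G[idx]
  pos <- array(0L, dim = dim(G))
  pos[idx] <- seq_len(n)
  ei <- integer(0); ej <- integer(0)
  d <- dim(G)
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    o <- DIRECTIONS_13[r, ]
    nb <- cbind(co[, 1] + o[1], co[, 2] + o[2], co[, 3] + o[3])
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    j <- integer(n); j[ok] <- pos[nb[ok, , drop = FALSE]]
    keep <- ok & j > 0L
    keep[keep] <- g[keep] == g[j[keep]]
    ei <- c(ei, which(keep)); ej <- c(ej, j[keep])
  }
  comp <- seq_len(n)
  if (length(ei)) {
    both <- c(ei, ej)
    repeat {
      prev <- comp
      mn <- pmin(comp[ei], comp[ej])
      v <- c(mn, mn)
      o <- order(both, v)
      first <- !duplicated(both[o])
      keys <- both[o][first]
      comp[keys] <- pmin(comp[keys], v[o][first])
      comp <- comp[comp]          # pointer jumping
      if (identical(prev, comp)) break
    }
  }
  zid <- match(comp, unique(comp))
  size <- tabulate(zid)
  gray <- g[match(unique(comp), comp)]
  f <- rl_stats(gray, size, ga$np,
                prefix = c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp",
                           "glv", "zv", "ze", "lglze", "hglze", "salgle",
                           "sahgle", "lalgle", "lahgle"))
  f
}
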