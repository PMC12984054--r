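# shared fixtures: small rendered cohorts are expensive, so cache them for
# the whole test session

.fixture_env <- new.env(parent = emptyenv())

phantom_fixture <- function(n = 6, seed = 101, shape = c(44, 44, 44), ...) {
  key <- paste0("coh_", n, "_", seed, "_", paste(shape, collapse = "x"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      phantom_config(n_patients = n, seed = seed, volume_shape = shape, ...))
  }
  .fixture_env[[key]]
}

# best-permutation agreement between two labelings with k classes
label_agreement <- function(a, b, k = 3) {
  tb <- table(factor(a, 1:k), factor(b, 1:k))
  perms <- permutations_k(k)
  max(apply(perms, 1, function(q) sum(tb[cbind(q, seq_len(k))]))) / sum(tb)
}

permutations_k <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_k(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# mildly smoothed random field (for interpolation tests on smooth inputs)
smooth_test_field <- function(arr, sigma = 2) {
  habstas:::smooth_field(arr, sigma)
}

# brute-force dilation oracle: pairwise voxel-centre distances
dilate_oracle <- function(mask, distance_mm) {
  d <- dim(mask$data)
  sp <- mask$spacing
  fg <- which(mask$data > 0L, arr.ind = TRUE)
  all_co <- arrayInd(seq_len(prod(d)), d)
  out <- array(0L, dim = d)
  for (i in seq_len(nrow(all_co))) {
    # minimum physical distance from this voxel centre to the foreground set
    dd <- sqrt(min(rowSums(sweep(fg, 2, all_co[i, ])^2 %*% diag(sp^2))))
    if (dd <= distance_mm) out[i] <- 1L
  }
  region_mask(out, sp, mask$origin)
}

# brute-force AUC by pairwise comparison counts
auc_bruteforce <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  s <- 0
  for (x in xs) s <- s + sum(x > ys) + 0.5 * sum(x == ys)
  s / (length(xs) * length(ys))
}

# brute-force Calinski-Harabasz from the textbook formula
ch_oracle <- function(X, lab) {
  X <- as.matrix(X)
  lab <- as.integer(factor(lab))
  n <- nrow(X); k <- max(lab)
  g <- colMeans(X)
  B <- 0; W <- 0
  for (j in seq_len(k)) {
    P <- X[lab == j, , drop = FALSE]
    cj <- colMeans(P)
    B <- B + nrow(P) * sum((cj - g)^2)
    for (r in seq_len(nrow(P))) W <- W + sum((P[r, ] - cj)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}
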