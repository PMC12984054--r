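#' ICC(2,1) reproducibility filter
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC per feature,
#' computed from ANOVA mean squares on a cases x raters matrix. Features are
#' kept when ICC exceeds the threshold in every supplied ratings matrix
#' (e.g. one inter-observer and one intra-observer matrix).
#'
#' @param ratings a named list of matrices, one per feature, each cases x
#'   raters/sessions; or a single such matrix for one feature.
#' @param threshold keep features with ICC strictly above this (default 0.75).
#' @return list with `icc` (named vector, worst ICC per feature across
#'   matrices) and `keep` (names of surviving features).
#' @export
icc_filter <- function(ratings, threshold = 0.75) {
  if (is.matrix(ratings)) ratings <- list(feature = ratings)
  icc <- vapply(ratings, function(m) {
    if (nrow(m) < 5 || ncol(m) < 2)
      stop("ICC needs >= 5 cases and >= 2 raters/sessions")
    icc21(m)
  }, 0)
  keep <- names(icc)[!is.na(icc) & icc > threshold]
  dropped_na <- names(icc)[is.na(icc)]
  if (length(dropped_na))
    warning("ICC undefined (zero between-case variance) for: ",
            paste(dropped_na, collapse = ", "))
  list(icc = icc, keep = keep)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement
icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= 0 || denom <= 0) return(NA_real_)
  (msr - mse) / denom
}

#' Fit a Z-score scaler on the training split and apply it everywhere
#'
#' Per-column mean and (sample) SD are estimated on training rows only and
#' applied to all rows. Training columns with zero SD are dropped with a
#' warning rather than divided by zero.
#'
#' @param table numeric data frame / matrix of features.
#' @param split character per row; `"train"` rows fit the scaler (`NULL` =
#'   all rows).
#' @return list with `table` (scaled), `center`, `scale`, `dropped`.
#' @export
zscore_fit_apply <- function(table, split = NULL) {
  X <- as.matrix(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  tr <- split == "train"
  if (!any(tr)) stop("training split is empty")
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  drop <- sdv == 0 | !is.finite(sdv)
  if (any(drop))
    warning("dropping zero-variance training columns: ",
            paste(colnames(X)[drop], collapse = ", "))
  Xs <- sweep(sweep(X[, !drop, drop = FALSE], 2, mu[!drop]), 2, sdv[!drop], "/")
  list(table = as.data.frame(Xs), center = mu[!drop], scale = sdv[!drop],
       dropped = colnames(X)[drop])
}

#' Mann-Whitney U screening of features against a binary label
#'
#' Two-sided Wilcoxon rank-sum test per feature on training rows; features
#' with p below `alpha` survive.
#'
#' @param table numeric feature data frame.
#' @param labels 0/1 vector aligned with rows.
#' @param alpha significance threshold (default 0.05).
#' @param split optional split tags; tests use training rows only.
#' @return list with `p` (named p-values) and `keep`.
#' @export
mannwhitney_filter <- function(table, labels, alpha = 0.05, split = NULL) {
  X <- as.matrix(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  tr <- split == "train"
  y <- labels[tr]
  if (min(table(y)) < 2) stop("each class needs at least 2 training members")
  p <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[tr, j]
    suppressWarnings(stats::wilcox.test(x[y == 1], x[y == 0])$p.value)
  }, 0)
  names(p) <- colnames(X)
  list(p = p, keep = colnames(X)[!is.na(p) & p < alpha])
}

#' Greedy Pearson redundancy pruning
#'
#' Feature pairs with |r| above the threshold (on training rows) are visited
#' in decreasing |r|; within a pair the feature with the larger Mann-Whitney
#' p-value is dropped (ties broken against the lexicographically later
#' name). No surviving pair exceeds the threshold.
#'
#' @param table numeric feature data frame (post U-test survivors).
#' @param u_p named p-values from [mannwhitney_filter()].
#' @param r_threshold correlation threshold (default 0.9).
#' @param split optional split tags; correlations use training rows only.
#' @return list with `keep` and `pruned` (data frame of dropped pairs).
#' @export
pearson_prune <- function(table, u_p, r_threshold = 0.9, split = NULL) {
  X <- as.matrix(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  R <- suppressWarnings(stats::cor(X[split == "train", , drop = FALSE]))
  R[is.na(R)] <- 0
  nm <- colnames(X)
  alive <- stats::setNames(rep(TRUE, length(nm)), nm)
  ut <- which(upper.tri(R) & abs(R) > r_threshold, arr.ind = TRUE)
  if (nrow(ut)) {
    ord <- order(-abs(R[ut]))
    ut <- ut[ord, , drop = FALSE]
    pruned <- list()
    for (q in seq_len(nrow(ut))) {
      a <- nm[ut[q, 1]]; b <- nm[ut[q, 2]]
      if (!alive[a] || !alive[b]) next
      pa <- u_p[[a]]; pb <- u_p[[b]]
      victim <- if (is.na(pa) || is.na(pb)) max(a, b)
        else if (pa > pb) a else if (pb > pa) b else max(a, b)
      alive[victim] <- FALSE
      pruned[[length(pruned) + 1L]] <-
        data.frame(kept = setdiff(c(a, b), victim), dropped = victim,
                   r = R[ut[q, 1], ut[q, 2]])
    }
    pruned <- if (length(pruned)) do.call(rbind, pruned) else NULL
  } else pruned <- NULL
  list(keep = nm[alive], pruned = pruned)
}

# plug-in mutual information (bits) between two small-integer vectors
mi_discrete <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  na <- max(a); nb <- max(b)
  tb <- matrix(tabulate(a + na * (b - 1L), na * nb), na, nb) / length(a)
  pa <- rowSums(tb); pb <- colSums(tb)
  nz <- tb > 0
  sum(tb[nz] * log2(tb[nz] / outer(pa, pb)[nz]))
}

# equal-frequency discretisation into `bins` levels
equal_freq_bins <- function(x, bins = 4L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(qs) < 3) return(as.integer(factor(x)))
  cut(x, qs, include.lowest = TRUE, labels = FALSE)
}

#' Greedy mRMR feature ranking (MID criterion)
#'
#' The first pick maximises mutual information with the label; each
#' subsequent pick maximises relevance minus mean redundancy against the
#' already-selected set. Continuous features are discretised into four
#' equal-frequency bins before the plug-in MI estimate; the procedure is
#' deterministic given the table.
#'
#' @param table numeric feature data frame.
#' @param labels binary label vector.
#' @param m number of features to rank (default 30, capped at availability).
#' @param split optional split tags; MI uses training rows only.
#' @return character vector of `m` feature names in selection order.
#' @export
mrmr_select <- function(table, labels, m = 30L, split = NULL) {
  if (m <= 0) stop("m must be positive")
  X <- as.matrix(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  tr <- split == "train"
  y <- labels[tr]
  m <- min(m, ncol(X))
  D <- apply(X[tr, , drop = FALSE], 2, equal_freq_bins)
  rel <- apply(D, 2, mi_discrete, b = y)
  selected <- character(0)
  red_sum <- stats::setNames(rep(0, ncol(X)), colnames(X))
  avail <- stats::setNames(rep(TRUE, ncol(X)), colnames(X))
  for (step in seq_len(m)) {
    score <- rel - if (step == 1) 0 else red_sum / (step - 1)
    score[!avail] <- -Inf
    pick <- names(which.max(score))
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    if (step < m) {
      add <- apply(D[, avail, drop = FALSE], 2, mi_discrete, b = D[, pick])
      red_sum[names(add)] <- red_sum[names(add)] + add
    }
  }
  selected
}

#' LASSO-penalised logistic selection with cross-validated lambda
#'
#' L1-penalised logistic regression over a 100-value log-spaced lambda grid;
#' lambda* minimises mean cross-validated binomial deviance with stratified
#' folds and a fixed seed. When lambda* zeroes every coefficient, the
#' largest lambda retaining at least one nonzero coefficient is used
#' instead (logged via a warning).
#'
#' @param table numeric feature data frame (mRMR survivors).
#' @param labels binary labels.
#' @param folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param split optional split tags; the fit uses training rows only.
#' @param rule lambda rule: `"min"` (minimum CV deviance, default) or
#'   `"1se"` (sparsest model within one standard error of the minimum).
#' @return list with `keep`, `coefficients` (nonzero, named), `lambda`,
#'   `cv_deviance` and the glmnet fit.
#' @export
lasso_select <- function(table, labels, folds = 10L, seed = 1L, split = NULL,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(table)
  if (is.null(split)) split <- rep("train", nrow(X))
  tr <- split == "train"
  Xtr <- X[tr, , drop = FALSE]; y <- labels[tr]
  if (ncol(Xtr) < 2) {
    # the L1 path needs >= 2 columns; a single survivor is kept as-is with
    # its unpenalised coefficient
    co <- stats::coef(stats::glm(y ~ ., binomial(),
                                 data.frame(Xtr, check.names = FALSE)))[-1]
    names(co) <- colnames(Xtr)
    return(list(keep = colnames(Xtr), coefficients = co, lambda = 0,
                cv_deviance = NULL, fit = NULL))
  }
  set.seed(seed)
  foldid <- stratified_folds(y, folds)
  cv <- glmnet::cv.glmnet(Xtr, y, family = "binomial", alpha = 1,
                          nlambda = 100, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  if (all(co == 0)) {
    nz <- cv$nzero > 0
    if (any(nz)) {
      lam <- max(cv$lambda[nz])
      co <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
      warning("lambda.min zeroed all coefficients; fell back to the knee lambda")
    }
  }
  list(keep = names(co)[co != 0], coefficients = co[co != 0], lambda = lam,
       cv_deviance = stats::setNames(cv$cvm, signif(cv$lambda, 4)), fit = cv)
}

stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Run the full feature-selection cascade on one region block
#'
#' Stages: optional ICC filter, Z-score (train-fitted), Mann-Whitney
#' screening, Pearson redundancy pruning, mRMR ranking, LASSO. Survivors are
#' nested stage to stage; all fitted quantities use the training split only.
#'
#' @param table numeric feature data frame (one region's columns).
#' @param labels binary labels per row.
#' @param split character split tags per row (`"train"` rows fit everything).
#' @param icc_keep optional character vector of ICC-approved feature names
#'   (columns outside it are dropped first); `NULL` skips the stage.
#' @param alpha,r_threshold,m,folds,seed stage parameters.
#' @return A `selection_report`: per-stage survivor lists, statistics, and
#'   `final` (the LASSO-selected features with a train-fitted scaler for
#'   downstream use).
#' @export
run_selection_cascade <- function(table, labels, split = NULL, icc_keep = NULL,
                                  alpha = 0.05, r_threshold = 0.9, m = 30L,
                                  folds = 10L, seed = 1L) {
  stages <- list()
  cols0 <- colnames(table)
  if (!is.null(icc_keep)) table <- table[, intersect(cols0, icc_keep), drop = FALSE]
  stages$icc <- colnames(table)
  zs <- suppressWarnings(zscore_fit_apply(table, split))
  stages$zscore <- colnames(zs$table)
  mw <- mannwhitney_filter(zs$table, labels, alpha, split)
  stages$utest <- mw$keep
  if (!length(mw$keep)) stop("no feature survived the Mann-Whitney screen")
  pp <- pearson_prune(zs$table[, mw$keep, drop = FALSE], mw$p, r_threshold, split)
  stages$pearson <- pp$keep
  mr <- mrmr_select(zs$table[, pp$keep, drop = FALSE], labels, m, split)
  stages$mrmr <- mr
  ls <- lasso_select(zs$table[, mr, drop = FALSE], labels, folds, seed, split)
  final <- ls$keep
  if (!length(final))
    warning("LASSO retained no feature; the final set is empty")
  stages$lasso <- final
  structure(list(stages = stages, u_p = mw$p, pruned = pp$pruned,
                 lasso = ls[c("coefficients", "lambda")],
                 scaler = zs[c("center", "scale")],
                 final = final),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  n <- vapply(x$stages, length, 0L)
  cat("<selection_report> survivors per stage:\n")
  print(n)
  invisible(x)
}
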