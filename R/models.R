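#' Model specification
#'
#' @param algorithm one of `"logistic"`, `"knn"`, `"rf"`, `"gbt"` (leaf-wise
#'   boosted trees), `"mlp"`.
#' @param grid list of named hyperparameter lists (one entry per candidate);
#'   `NULL` uses a small fixed default grid.
#' @param folds tuning folds (default 5).
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("logistic", "knn", "rf", "gbt", "mlp"),
                       grid = NULL, folds = 5L) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid)) stop("hyperparameter grid must be nonempty")
  structure(list(algorithm = algorithm, grid = grid, folds = as.integer(folds)),
            class = "model_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    logistic = list(list()),
    knn = lapply(c(3, 5, 7, 11), function(k) list(k = k)),
    rf = do.call(c, lapply(c(100, 300), function(nt)
      lapply(c(0, 6), function(d) list(num_trees = nt, max_depth = d)))),
    gbt = do.call(c, lapply(c(50, 150), function(nr)
      lapply(c(3, 6), function(d) list(nrounds = nr, max_depth = d, eta = 0.1)))),
    mlp = do.call(c, lapply(c(4, 16), function(sz)
      lapply(c(1e-3, 1e-1), function(dec) list(size = sz, decay = dec)))))
}

#' Default specification list covering all five algorithm families
#' @param folds tuning folds.
#' @return list of [model_spec()] objects.
#' @export
default_model_specs <- function(folds = 5L) {
  lapply(c("logistic", "knn", "rf", "gbt", "mlp"), model_spec, folds = folds)
}

fit_algorithm <- function(algorithm, hyper, X, y, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  fit <- switch(algorithm,
    logistic = {
      df <- data.frame(X, .y = y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., binomial(), df))
    },
    knn = list(X = X, y = y, k = hyper$k),
    rf = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                        num.trees = hyper$num_trees,
                        max.depth = if (hyper$max_depth > 0) hyper$max_depth else NULL,
                        probability = TRUE, seed = seed, num.threads = 1),
    gbt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hyper$max_depth,
                    eta = hyper$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = hyper$nrounds,
      verbose = 0),
    mlp = nnet::nnet(X, y, size = hyper$size, decay = hyper$decay,
                     entropy = TRUE, maxit = 200, trace = FALSE,
                     MaxNWts = 10000))
  list(algorithm = algorithm, hyper = hyper, fit = fit,
       features = colnames(X), seed = seed)
}

predict_prob_fit <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  p <- switch(model$algorithm,
    logistic = stats::predict(model$fit,
                              newdata = data.frame(X, check.names = FALSE),
                              type = "response"),
    knn = {
      set.seed(model$seed)
      k <- min(model$fit$k, nrow(model$fit$X))
      pr <- class::knn(model$fit$X, X, factor(model$fit$y, levels = c(0, 1)),
                       k = k, prob = TRUE)
      won <- attr(pr, "prob")
      ifelse(pr == "1", won, 1 - won)
    },
    rf = stats::predict(model$fit, data = X, num.threads = 1)$predictions[, "1"],
    gbt = stats::predict(model$fit, xgboost::xgb.DMatrix(X)),
    mlp = as.numeric(stats::predict(model$fit, X)))
  pmin(pmax(as.numeric(p), 0), 1)
}

# simple rank-based AUC (tie-corrected); the inferential version lives in
# evaluation.R
auc_simple <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

tune_one_spec <- function(spec, X, y, seed) {
  folds <- spec$folds
  set.seed(seed)
  foldid <- stratified_folds(y, folds)
  # guard against single-class folds on tiny/imbalanced data
  while (min(table(foldid, y)) == 0 && folds > 2) {
    folds <- folds - 1
    set.seed(seed)
    foldid <- stratified_folds(y, folds)
  }
  cv_auc <- vapply(seq_along(spec$grid), function(gi) {
    hyper <- spec$grid[[gi]]
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- fit_algorithm(spec$algorithm, hyper, X[tr, , drop = FALSE], y[tr],
                           seed = seed + f)
      oof[!tr] <- predict_prob_fit(fit, X[!tr, , drop = FALSE])
    }
    auc_simple(oof, y)
  }, 0)
  best <- which.max(cv_auc)
  list(hyper = spec$grid[[best]], cv_auc = cv_auc[best], all_cv_auc = cv_auc,
       folds_used = folds)
}

#' Train one region model: tune all algorithms, pick the validation winner
#'
#' Every supplied algorithm is tuned by stratified cross-validation on the
#' training split (grid search on CV AUC), refit on the full training split,
#' and scored on the validation split; the winner is the algorithm with the
#' highest validation AUC (ties broken by the fixed order of `specs`). The
#' validation labels influence nothing except this winner pick. The binary
#' operating threshold is Youden-optimal on the training split.
#'
#' @param X numeric feature matrix/data frame (all rows, final features).
#' @param y binary labels.
#' @param split character per row: `"train"`, `"val"` (and optionally
#'   `"test"`, unused here).
#' @param specs list of [model_spec()]; default all five families.
#' @param seed RNG seed.
#' @param region_tag label stored with the model (e.g. `"Habitat"`).
#' @return A `trained_model` with the fitted winner, per-algorithm report,
#'   threshold, and metadata.
#' @export
train_region_model <- function(X, y, split, specs = default_model_specs(),
                               seed = 1L, region_tag = "region") {
  X <- as.matrix(X)
  if (!ncol(X)) stop("no features supplied")
  tr <- split == "train"; va <- split == "val"
  if (length(unique(y[tr])) < 2) stop("training split needs both classes")
  report <- list()
  best <- NULL
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    tuned <- tune_one_spec(spec, X[tr, , drop = FALSE], y[tr], seed)
    fit <- fit_algorithm(spec$algorithm, tuned$hyper, X[tr, , drop = FALSE],
                         y[tr], seed)
    val_auc <- if (any(va)) auc_simple(predict_prob_fit(fit, X[va, , drop = FALSE]),
                                       y[va]) else tuned$cv_auc
    report[[spec$algorithm]] <- list(cv_auc = tuned$cv_auc, val_auc = val_auc,
                                     hyper = tuned$hyper)
    if (is.null(best) || val_auc > best$val_auc + 1e-12)
      best <- list(fit = fit, val_auc = val_auc, algorithm = spec$algorithm,
                   hyper = tuned$hyper, spec = spec)
  }
  ptrain <- predict_prob_fit(best$fit, X[tr, , drop = FALSE])
  structure(list(fit = best$fit, algorithm = best$algorithm,
                 hyper = best$hyper, region_tag = region_tag,
                 features = colnames(X),
                 threshold = youden_threshold(ptrain, y[tr]),
                 val_auc = best$val_auc, report = report, seed = seed),
            class = "trained_model")
}

youden_threshold <- function(p, y) {
  cand <- sort(unique(c(0.5, p)))
  j <- vapply(cand, function(t) {
    sens <- mean(p[y == 1] >= t); spec <- mean(p[y == 0] < t)
    sens + spec - 1
  }, 0)
  cand[which.max(j)]
}

#' Predict probabilities from a trained model
#' @param object a `trained_model`.
#' @param newdata feature matrix/data frame containing the model's features.
#' @param ... unused.
#' @return numeric probabilities in `[0,1]`.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict_prob_fit(object$fit, as.matrix(newdata))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s> winner %s (val AUC %.3f), %d features, threshold %.3f\n",
              x$region_tag, x$algorithm, x$val_auc, length(x$features), x$threshold))
  invisible(x)
}

#' Train the clinical model
#'
#' Same protocol as [train_region_model()] on the (possibly single-column)
#' clinical design restricted to the supplied predictors — by convention the
#' significant set from the univariable/multivariable logistic analysis.
#'
#' @param design numeric clinical design matrix (see [clinical_design()]).
#' @param predictors character vector of selected predictor columns.
#' @inheritParams train_region_model
#' @return A `trained_model` tagged `"Clinical"`.
#' @export
train_clinical_model <- function(design, predictors, y, split,
                                 specs = default_model_specs(), seed = 1L) {
  if (!length(predictors))
    stop("empty clinical predictor set; inspect the logistic regression report")
  train_region_model(design[, predictors, drop = FALSE], y, split, specs,
                     seed, region_tag = "Clinical")
}

#' Numeric design matrix from a clinical table
#'
#' Binary CT signs and marker categories are 0/1-encoded, tumor location
#' becomes dummy columns against the right-upper-lobe reference, and sizes /
#' age stay numeric.
#'
#' @param clinical data frame with the standard clinical columns.
#' @return numeric matrix, one row per patient.
#' @export
clinical_design <- function(clinical) {
  bin <- function(x, hi) as.numeric(x == hi)
  out <- cbind(
    Age = clinical$Age,
    Lwts = clinical$Lwts,
    Mwts = clinical$Mwts,
    Sex_male = bin(clinical$Sex, "Male"),
    Smoking = bin(clinical$Smoking_history, "Yes"),
    CEA_high = bin(clinical$CEA, ">5.0"),
    SCCA_high = bin(clinical$SCCA, ">1.5"),
    NSE_high = bin(clinical$NSE, ">17.0"),
    CYFRA_high = bin(clinical$CYFRA, ">3.3"),
    Lobulation = bin(clinical$Lobulation, "Present"),
    Spiculation = bin(clinical$Spiculation, "Present"),
    Bronchial_cutoff = bin(clinical$Bronchial_cutoff, "Present"),
    Air_bronchogram = bin(clinical$Air_bronchogram, "Present"),
    Vacuole = bin(clinical$Vacuole, "Present"))
  loc <- factor(clinical$Location, levels = c("RUL", "RML", "RLL", "LUL", "LLL"))
  dummies <- stats::model.matrix(~ loc)[, -1, drop = FALSE]
  colnames(dummies) <- paste0("Loc_", sub("^loc", "", colnames(dummies)))
  cbind(out, dummies)
}

#' Fuse habitat, peritumoral and clinical models by probability stacking
#'
#' Out-of-fold (stratified 5-fold) base-model probabilities on the training
#' split form the design for an unpenalised logistic meta-learner; at
#' inference the refit base models predict and the meta-learner combines. A
#' simple probability average is available as `method = "average"`.
#'
#' @param models named list of `trained_model`s (e.g. Habitat, Peri3mm,
#'   Clinical).
#' @param X_list list of feature matrices aligned with `models` (all rows).
#' @param y binary labels; `split` as elsewhere.
#' @param folds stacking folds (default 5).
#' @param seed RNG seed.
#' @param method `"stack"` (default) or `"average"`.
#' @return A `combined_model` with `predict()` support.
#' @export
fuse_combined <- function(models, X_list, y, split, folds = 5L, seed = 1L,
                          method = c("stack", "average")) {
  method <- match.arg(method)
  if (length(models) < 2 || is.null(names(models)))
    stop("supply a named list of at least two base models")
  if (!identical(names(models), names(X_list)))
    stop("models and X_list must align by name")
  tr <- split == "train"
  ytr <- y[tr]
  meta <- NULL
  if (method == "stack") {
    set.seed(seed)
    foldid <- stratified_folds(ytr, folds)
    oof <- matrix(NA_real_, sum(tr), length(models),
                  dimnames = list(NULL, names(models)))
    for (mi in seq_along(models)) {
      m <- models[[mi]]
      Xtr <- as.matrix(X_list[[mi]])[tr, m$features, drop = FALSE]
      for (f in seq_len(folds)) {
        inf <- foldid != f
        fit <- fit_algorithm(m$algorithm, m$hyper, Xtr[inf, , drop = FALSE],
                             ytr[inf], seed = seed + f)
        oof[!inf, mi] <- predict_prob_fit(fit, Xtr[!inf, , drop = FALSE])
      }
    }
    df <- as.data.frame(oof)
    df$y <- ytr
    meta <- suppressWarnings(stats::glm(y ~ ., binomial(), df))
  }
  base_tr <- vapply(seq_along(models), function(mi)
    predict_prob_fit(models[[mi]]$fit, as.matrix(X_list[[mi]])[tr, , drop = FALSE]),
    numeric(sum(tr)))
  colnames(base_tr) <- names(models)
  ptrain <- if (method == "stack")
    stats::predict(meta, newdata = as.data.frame(base_tr), type = "response")
  else rowMeans(base_tr)
  structure(list(models = models, meta = meta, method = method,
                 oof = if (method == "stack") oof,
                 threshold = youden_threshold(ptrain, ytr),
                 region_tag = "Combined", seed = seed),
            class = "combined_model")
}

#' @export
predict.combined_model <- function(object, X_list, ...) {
  base <- vapply(seq_along(object$models), function(mi)
    predict_prob_fit(object$models[[mi]]$fit, as.matrix(X_list[[mi]])),
    numeric(nrow(as.matrix(X_list[[1]]))))
  colnames(base) <- names(object$models)
  if (object$method == "stack")
    as.numeric(stats::predict(object$meta, newdata = as.data.frame(base),
                              type = "response"))
  else rowMeans(base)
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("<combined_model> %s fusion of: %s\n", x$method,
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}
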