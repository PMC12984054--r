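#' Stratified cohort splitting
#'
#' Random assignment of patients to named splits at fixed ratios, stratified
#' by label so prevalence is balanced (the label-blind variant is available
#' with `stratify = FALSE`).
#'
#' @param labels binary labels (used for stratification and feasibility
#'   checks).
#' @param ratios named numeric ratios summing to 1
#'   (default `c(train = 0.7, val = 0.3)`).
#' @param seed RNG seed.
#' @param stratify logical.
#' @return character vector of split names per patient.
#' @export
split_cohort <- function(labels, ratios = c(train = 0.7, val = 0.3), seed = 1L,
                         stratify = TRUE) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (is.null(names(ratios))) stop("ratios must be named")
  n <- length(labels)
  set.seed(seed)
  assign_block <- function(idx) {
    m <- length(idx)
    counts <- round(ratios * m)
    counts[length(counts)] <- m - sum(counts[-length(counts)])
    if (any(counts < 0)) stop("split ratios infeasible for class sizes")
    sample(rep(names(ratios), counts))
  }
  out <- character(n)
  if (stratify) {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < 2) stop("each class needs at least 2 members")
      out[idx] <- assign_block(idx)
    }
  } else out <- assign_block(seq_len(n))
  for (sp in names(ratios))
    if (stratify && min(table(labels[out == sp])) < 1)
      stop(sprintf("split '%s' lost a class; ratios infeasible", sp))
  out
}

region_model_tag <- function(block) {
  switch(block,
         intra = "Intra",
         peri1 = "Peri1mm", peri3 = "Peri3mm", peri5 = "Peri5mm",
         hab = "Habitat", block)
}

#' Run the full habitat + peritumoral radiomics pipeline
#'
#' Orchestrates: lung-window preprocessing, habitat clustering (with
#' cohort-wide k selection when `k` is `NULL`), peritumoral rings, feature
#' extraction, KNN imputation, the per-region selection cascade, clinical
#' regression and model, per-region model training, fusion of the configured
#' base models, and the evaluation battery. Deterministic given `seed`.
#'
#' @param cohort list of patients (e.g. [generate_cohort()] output) forming
#'   the train/validation pool.
#' @param test_cohort optional external test cohort; when absent the
#'   combined model is evaluated on train/val only, with a warning.
#' @param split_ratios train/val ratios for `cohort`.
#' @param ring_distances peritumoral distances in mm.
#' @param k habitat count; `NULL` selects it by mean CH over `k_grid`.
#' @param k_grid candidate habitat counts.
#' @param regions region blocks to model (subset of
#'   `c("intra","peri1","peri3","peri5","hab")`).
#' @param fuse character vector of base model tags entering the combined
#'   model (default Habitat, Peri3mm, Clinical).
#' @param specs list of [model_spec()] per algorithm family.
#' @param m_mrmr mRMR size.
#' @param seed master seed; all stage seeds derive from it.
#' @param window a [window_spec()].
#' @return A `habstas_run` list: habitat selection, feature table, selection
#'   reports, models, predictions, and the [evaluate_models()] report.
#' @export
run_all <- function(cohort, test_cohort = NULL,
                    split_ratios = c(train = 0.7, val = 0.3),
                    ring_distances = c(1, 3, 5),
                    k = NULL, k_grid = 2:8,
                    regions = c("intra", "peri1", "peri3", "peri5", "hab"),
                    fuse = c("Habitat", "Peri3mm", "Clinical"),
                    specs = default_model_specs(),
                    m_mrmr = 30L, seed = 1L, window = window_spec()) {
  labels <- vapply(cohort, `[[`, 0L, "stas")
  split <- split_cohort(labels, split_ratios, seed = seed)
  all_pat <- cohort
  if (!is.null(test_cohort)) {
    all_pat <- c(cohort, test_cohort)
    split <- c(split, rep("test", length(test_cohort)))
    labels <- c(labels, vapply(test_cohort, `[[`, 0L, "stas"))
  } else {
    warning("no external test cohort; models evaluated on train/val only")
  }

  # habitat stage
  want_hab <- "hab" %in% regions
  fms <- NULL; ksel <- NULL; habitat_maps <- NULL
  if (want_hab) {
    fms <- lapply(all_pat, function(p)
      local_feature_map(apply_window(p$ct, window), p$tumor_mask))
    if (is.null(k)) {
      ksel <- suppressWarnings(select_k(fms, k_grid, seed = seed))
      k <- ksel$k_star
    }
    habitat_maps <- lapply(seq_along(fms), function(i)
      cluster_habitats(fms[[i]], k, seed = seed + i))
  }

  # feature extraction + imputation
  table <- suppressWarnings(
    extract_all(all_pat, ring_distances, habitat_maps, window,
                regions = regions))
  table <- knn_impute(table, split)

  # per-region selection + model
  blocks <- intersect(c("intra", paste0("peri", ring_distances), "hab"), regions)
  sel_reports <- list(); models <- list(); X_by_tag <- list()
  for (b in blocks) {
    pat <- if (b == "hab") "^hab[0-9]+_" else paste0("^", b, "_")
    cols <- grep(pat, colnames(table), value = TRUE)
    rep_b <- run_selection_cascade(table[, cols, drop = FALSE], labels,
                                   split, m = m_mrmr, seed = seed)
    if (!length(rep_b$final)) {
      warning(sprintf("region %s: empty LASSO set; using its top mRMR feature", b))
      rep_b$final <- rep_b$stages$mrmr[1]
    }
    tag <- region_model_tag(b)
    sel_reports[[tag]] <- rep_b
    Xb <- scale(as.matrix(table[, names(rep_b$scaler$center), drop = FALSE]),
                center = rep_b$scaler$center, scale = rep_b$scaler$scale)
    Xb <- Xb[, rep_b$final, drop = FALSE]
    X_by_tag[[tag]] <- Xb
    models[[tag]] <- train_region_model(Xb, labels, split, specs,
                                        seed = seed, region_tag = tag)
  }

  # clinical analysis + model
  clin <- do.call(rbind, lapply(all_pat, `[[`, "clinical"))
  design <- clinical_design(clin)
  tr <- split == "train"
  reg_multi <- logistic_regression(design[tr, , drop = FALSE], labels[tr],
                                   "multivariable")
  predictors <- reg_multi$variable[reg_multi$p < 0.05]
  if (!length(predictors)) {
    uni <- attr(reg_multi, "univariable")
    predictors <- uni$variable[uni$p < 0.05]
    if (length(predictors)) {
      warning("no multivariable-significant clinical predictor; falling back to the univariable-significant set")
    } else {
      predictors <- uni$variable[which.min(uni$p)]
      warning("no univariable-significant clinical predictor; using the smallest-p variable")
    }
  }
  models[["Clinical"]] <- train_clinical_model(design, predictors, labels,
                                               split, specs, seed = seed)
  X_by_tag[["Clinical"]] <- design[, predictors, drop = FALSE]

  # fusion
  fuse <- intersect(fuse, names(models))
  combined <- NULL
  if (length(fuse) >= 2) {
    combined <- fuse_combined(models[fuse], X_by_tag[fuse], labels, split,
                              seed = seed)
  }

  # predictions + evaluation
  preds <- list()
  for (tag in names(models)) {
    p <- predict(models[[tag]], X_by_tag[[tag]])
    preds[[tag]] <- data.frame(model = tag, split = split, prob = p,
                               label = labels,
                               threshold = models[[tag]]$threshold)
  }
  if (!is.null(combined)) {
    p <- predict(combined, X_by_tag[fuse])
    preds[["Combined"]] <- data.frame(model = "Combined", split = split,
                                      prob = p, label = labels,
                                      threshold = combined$threshold)
  }
  predictions <- do.call(rbind, preds)
  report <- evaluate_models(predictions)

  structure(list(split = split, k = k, k_selection = ksel,
                 feature_table = table, selection = sel_reports,
                 regression = reg_multi, clinical_predictors = predictors,
                 models = models, combined = combined,
                 predictions = predictions, report = report, seed = seed),
            class = "habstas_run")
}

#' @export
print.habstas_run <- function(x, ...) {
  cat(sprintf("<habstas_run> k = %d, models: %s\n", x$k,
              paste(c(names(x$models), if (!is.null(x$combined)) "Combined"),
                    collapse = ", ")))
  print(x$report)
  invisible(x)
}
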