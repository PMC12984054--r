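#' AUC with DeLong variance and normal 95% CI
#'
#' The AUC is the tie-corrected Mann-Whitney statistic
#' `U / (n1 * n0)` (ties count one half). Its variance comes from the DeLong
#' structural components: `V10_i = mean_j psi(x_i, y_j)` over controls for
#' each case and vice versa, with `psi = 1, 1/2, 0` for win/tie/loss. The CI
#' is `AUC +/- 1.96 * SE`, truncated to `[0, 1]`.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param labels binary 0/1 labels (both classes present).
#' @return list with `auc`, `var`, `ci` (length-2), `n1`, `n0`.
#' @export
auc_delong <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  # structural components via ranks (O(n log n))
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_x) / n0            # per-case components
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1   # per-control components
  auc <- mean(v10)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  v <- s10 / n1 + s01 / n0
  se <- sqrt(max(v, 0))
  list(auc = auc, var = v,
       ci = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
       n1 = n1, n0 = n0)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided p-value for the difference of AUCs of two score vectors on the
#' same patients, using the covariance of their DeLong structural
#' components.
#'
#' @param scores_a,scores_b score vectors on the same patients.
#' @param labels binary labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  comp <- function(scores) {
    x <- scores[labels == 1]; y <- scores[labels == 0]
    n1 <- length(x); n0 <- length(y)
    r_all <- rank(c(x, y), ties.method = "average")
    v10 <- (r_all[seq_len(n1)] - rank(x, ties.method = "average")) / n0
    v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y, ties.method = "average")) / n1
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- comp(scores_a); b <- comp(scores_b)
  n1 <- length(a$v10); n0 <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(vd) || vd <= 0) {
    warning("non-positive variance of the AUC difference; p set to 1")
    return(list(auc_a = a$auc, auc_b = b$auc, z = 0, p = 1))
  }
  z <- (a$auc - b$auc) / sqrt(vd)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Confusion metrics at a threshold
#'
#' @param scores probabilities; `labels` binary; `threshold` in `[0,1]`
#'   (score >= threshold predicts positive).
#' @return named vector: accuracy, sensitivity, specificity, ppv, npv
#'   (`NaN` sentinel where a denominator is empty).
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
    npv = if (tn + fn > 0) tn / (tn + fn) else NaN)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping on predicted probabilities;
#' `chi2 = sum (O - E)^2 / (E (1 - E/n_g))` referred to a chi-square with
#' `groups - fitted_df` degrees of freedom. Empty bins (tied probabilities)
#' are merged with their neighbour. The classical correction `fitted_df = 2`
#' applies when the probabilities were fitted on the same data; for
#' externally supplied (exogenous) probabilities the uncorrected reference
#' `fitted_df = 0` is the calibrated choice.
#'
#' @param probabilities predicted event probabilities.
#' @param labels binary outcomes.
#' @param bins number of risk groups (default 10).
#' @param fitted_df degrees of freedom absorbed by in-sample fitting
#'   (default 2, the classical correction).
#' @return list with `chi2`, `df`, `p`, and the per-bin table.
#' @export
hosmer_lemeshow <- function(probabilities, labels, bins = 10L, fitted_df = 2L) {
  n <- length(labels)
  if (n < bins) stop("need at least as many observations as bins")
  br <- unique(stats::quantile(probabilities, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  g <- if (length(br) < 2) rep(1L, n)
    else cut(probabilities, br, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(g)), function(b) {
    idx <- g == b
    c(n = sum(idx), obs = sum(labels[idx]), exp = sum(probabilities[idx]))
  }))
  ok <- tab[, "exp"] > 0 & tab[, "exp"] < tab[, "n"]
  chi2 <- sum((tab[ok, "obs"] - tab[ok, "exp"])^2 /
                (tab[ok, "exp"] * (1 - tab[ok, "exp"] / tab[ok, "n"])))
  df <- max(1L, sum(ok) - fitted_df)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = tab)
}

#' Decision-curve net benefit
#'
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)` per threshold probability, with
#' the treat-all and treat-none reference strategies.
#'
#' @param scores predicted probabilities; `labels` binary outcomes.
#' @param thresholds grid in `[0, 1)` (default 0 to 0.99 by 0.01).
#' @return data frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0, 0.99, by = 0.01)) {
  n <- length(labels)
  prev <- mean(labels == 1)
  out <- t(vapply(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & labels == 1) / n
    fp <- sum(pred & labels == 0) / n
    w <- if (pt < 1) pt / (1 - pt) else Inf
    c(net_benefit = tp - fp * w,
      treat_all = prev - (1 - prev) * w)
  }, c(net_benefit = 0, treat_all = 0)))
  data.frame(threshold = thresholds, out, treat_none = 0)
}

#' Odds ratio with Wald 95% CI from a 2x2 table
#'
#' Counts are `(a, b, c, d)` = (exposed case, exposed control, unexposed
#' case, unexposed control). Zero cells trigger the Haldane-Anscombe 0.5
#' correction with a warning; an all-zero row or column returns `NA`
#' sentinels.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list with `or`, `ci`, `log_se`.
#' @export
odds_ratio_wald <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), log_se = NA_real_))
  if (any(cnt == 0)) {
    warning("zero cell; applying Haldane-Anscombe 0.5 correction")
    cnt <- cnt + 0.5
  }
  or <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
  se <- sqrt(sum(1 / cnt))
  list(or = or, ci = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se), log_se = se)
}

# Jeffreys-prior (Firth-style) penalised logistic fit by Newton iterations
firth_logistic <- function(Xd, y, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(Xd))
  Iinv <- NULL
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- Xd * w
    I <- crossprod(Xd, XW) + diag(1e-8, ncol(Xd))
    Iinv <- solve(I)
    h <- rowSums((Xd %*% Iinv) * XW)
    U <- crossprod(Xd, (y - mu) + h * (0.5 - mu))
    step <- as.numeric(Iinv %*% U)
    # damp oversized Newton steps for stability under quasi-separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = beta, vcov = Iinv)
}

#' Univariable / multivariable logistic regression report
#'
#' Univariable mode fits one logistic model per column and reports Wald OR,
#' 95% CI and p; multivariable mode jointly fits the variables that were
#' univariably significant (p < `alpha`). Complete separation (detected by
#' diverging coefficients or non-convergence) triggers a Jeffreys-penalised
#' (Firth-style) refit, flagged in the report.
#'
#' @param design numeric design matrix (no intercept column).
#' @param labels binary outcome.
#' @param mode `"univariable"` or `"multivariable"`.
#' @param alpha univariable significance gate for the multivariable design.
#' @return A `regression_report` data frame: variable, or, ci_low, ci_high,
#'   p, mode, firth flag.
#' @export
logistic_regression <- function(design, labels, mode = c("univariable", "multivariable"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  design <- as.matrix(design)
  const <- apply(design, 2, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  if (any(const)) {
    warning("dropping constant design columns: ",
            paste(colnames(design)[const], collapse = ", "))
    design <- design[, !const, drop = FALSE]
  }
  fit_one <- function(cols) {
    Xd <- cbind(`(Intercept)` = 1, design[, cols, drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(Xd, labels, family = binomial()))
    co <- fit$coefficients
    separated <- !fit$converged || anyNA(co) || any(abs(co[-1]) > 15)
    if (separated) {
      ff <- firth_logistic(Xd, labels)
      co <- ff$coefficients
      se <- sqrt(diag(ff$vcov))
    } else {
      eta <- as.numeric(Xd %*% co)
      mu <- 1 / (1 + exp(-eta))
      I <- crossprod(Xd, Xd * (mu * (1 - mu)))
      se <- sqrt(diag(solve(I)))
    }
    z <- co / se
    data.frame(variable = cols,
               or = exp(co[-1]),
               ci_low = exp(co[-1] - stats::qnorm(0.975) * se[-1]),
               ci_high = exp(co[-1] + stats::qnorm(0.975) * se[-1]),
               p = 2 * stats::pnorm(-abs(z[-1])),
               firth = separated,
               row.names = NULL)
  }
  if (mode == "univariable") {
    out <- do.call(rbind, lapply(colnames(design), fit_one))
  } else {
    uni <- do.call(rbind, lapply(colnames(design), fit_one))
    sig <- uni$variable[uni$p < alpha]
    if (!length(sig)) {
      out <- uni[0, ]
    } else {
      out <- fit_one(sig)
    }
    attr(out, "univariable") <- uni
  }
  out$mode <- rep(mode, nrow(out))
  class(out) <- c("regression_report", class(out))
  out
}

#' Cohen's kappa for two binary raters
#'
#' @param ratings_a,ratings_b binary ratings on the same cases.
#' @return kappa (NA sentinel when expected agreement is 1).
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) stop("rating vectors must align")
  po <- mean(ratings_a == ratings_b)
  pe <- mean(ratings_a == 1) * mean(ratings_b == 1) +
    mean(ratings_a == 0) * mean(ratings_b == 0)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Evaluation report for a set of models across cohort splits
#'
#' Per model and split: AUC with DeLong CI, confusion metrics at the model's
#' frozen (training-Youden) threshold, Hosmer-Lemeshow calibration, and the
#' decision curve. Also returns the pairwise DeLong p-matrix per split.
#'
#' @param predictions data frame with columns `model`, `split`, `prob`,
#'   `label`, `threshold`.
#' @return An `eval_report` list: `metrics` (data frame), `delong` (list of
#'   p-matrices per split), `curves` (decision curves).
#' @export
evaluate_models <- function(predictions) {
  stopifnot(all(c("model", "split", "prob", "label", "threshold") %in%
                  colnames(predictions)))
  metrics <- list(); curves <- list(); delong <- list()
  for (sp in unique(predictions$split)) {
    sub <- predictions[predictions$split == sp, ]
    models <- unique(sub$model)
    for (mo in models) {
      d <- sub[sub$model == mo, ]
      ad <- auc_delong(d$prob, d$label)
      cm <- confusion_metrics(d$prob, d$label, d$threshold[1])
      hl <- tryCatch(hosmer_lemeshow(d$prob, d$label),
                     error = function(e) list(chi2 = NA, p = NA))
      metrics[[paste(mo, sp)]] <- data.frame(
        model = mo, split = sp, auc = ad$auc, ci_low = ad$ci[1],
        ci_high = ad$ci[2], t(cm), hl_chi2 = hl$chi2, hl_p = hl$p,
        row.names = NULL)
      curves[[paste(mo, sp)]] <- cbind(model = mo, split = sp,
                                       decision_curve(d$prob, d$label))
    }
    pm <- matrix(NA_real_, length(models), length(models),
                 dimnames = list(models, models))
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i >= j) next
      da <- sub[sub$model == models[i], ]
      db <- sub[sub$model == models[j], ]
      pm[i, j] <- pm[j, i] <-
        delong_paired_test(da$prob, db$prob, da$label)$p
    }
    delong[[sp]] <- pm
  }
  structure(list(metrics = do.call(rbind, metrics),
                 delong = delong,
                 curves = do.call(rbind, curves)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$metrics[, c("model", "split", "auc", "ci_low", "ci_high", "accuracy",
                      "sensitivity", "specificity")], digits = 3)
  invisible(x)
}
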