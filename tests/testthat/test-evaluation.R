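test_that("AUC matches pairwise enumeration on small instances", {
  res <- auc_delong(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(res$auc, 0.75)
  # perfect separation: AUC 1, zero variance
  perf <- auc_delong(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_equal(perf$var, 0)
  # all scores tied: AUC 0.5
  expect_equal(auc_delong(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(auc_delong(runif(5), rep(1, 5)), "both classes")
  # CI is ordered and contains the AUC
  set.seed(1)
  r <- auc_delong(runif(40), rbinom(40, 1, 0.5))
  expect_lte(r$ci[1], r$auc); expect_gte(r$ci[2], r$auc)
})

test_that("AUC equals the brute-force pairwise count to 1e-12", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)   # force ties
    expect_equal(auc_delong(s, y)$auc, auc_bruteforce(s, y), tolerance = 1e-12)
  }
})

test_that("the paired DeLong test behaves as a two-sided z-test", {
  set.seed(23)
  y <- rbinom(120, 1, 0.4)
  a <- plogis(rnorm(120) + y)
  expect_equal(delong_paired_test(a, a, y)$p, 1)
  b <- plogis(rnorm(120) + 0.5 * y)
  f <- delong_paired_test(a, b, y)
  g <- delong_paired_test(b, a, y)
  expect_equal(f$p, g$p)
  expect_equal(f$z, -g$z)
  # agreement with a paired bootstrap within 0.05
  set.seed(24)
  boot <- replicate(2000, {
    idx <- sample(120, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_delong(a[idx], y[idx])$auc - auc_delong(b[idx], y[idx])$auc
  })
  boot <- boot[!is.na(boot)]
  d0 <- f$auc_a - f$auc_b
  p_boot <- 2 * min(mean(boot - d0 <= -d0) + 0.5 / length(boot),
                    mean(boot - d0 >= d0) + 0.5 / length(boot))
  p_boot <- min(p_boot, 1)
  expect_lt(abs(f$p - p_boot), 0.05 + 1e-9)
})

test_that("DeLong variance and paired test agree with an independent implementation", {
  set.seed(29)
  y <- rbinom(150, 1, 0.4)
  a <- plogis(rnorm(150) + 1.2 * y)
  b <- plogis(rnorm(150) + 0.6 * y)
  ours <- auc_delong(a, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, a, quiet = TRUE),
                                       method = "delong"))
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  # 1.96 here vs qnorm(0.975) in the reference: agree to ~1e-4
  expect_equal(ours$ci[1], as.numeric(ref[1]), tolerance = 1e-4)
  expect_equal(ours$ci[2], as.numeric(ref[3]), tolerance = 1e-4)
  ptest <- delong_paired_test(a, b, y)
  pref <- suppressMessages(pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                                          pROC::roc(y, b, quiet = TRUE),
                                          method = "delong"))
  expect_equal(ptest$p, pref$p.value, tolerance = 1e-8)
})

test_that("confusion metrics come straight from the 2x2", {
  scores <- c(rep(0.9, 30), rep(0.8, 10), rep(0.2, 5), rep(0.1, 55))
  labels <- c(rep(1, 30), rep(0, 10), rep(1, 5), rep(0, 55))
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["ppv"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 30 / 35)
  expect_equal(unname(m["specificity"]), 55 / 65)
  # threshold 0: everything positive
  m0 <- confusion_metrics(scores, labels, 0)
  expect_equal(unname(m0["sensitivity"]), 1)
  expect_equal(unname(m0["specificity"]), 0)
  # threshold above 1: nothing positive, NPV = 1 - prevalence
  m1 <- confusion_metrics(scores, labels, 1.01)
  expect_equal(unname(m1["sensitivity"]), 0)
  expect_equal(unname(m1["npv"]), 1 - mean(labels))
  expect_true(is.nan(m1["ppv"]))
})

test_that("Hosmer-Lemeshow is calibrated under the null and powered against it", {
  set.seed(31)
  # null: probabilities are the true Bernoulli parameters
  pvals <- vapply(1:60, function(i) {
    p <- runif(2000, 0.05, 0.95)
    # exogenous probabilities: no fitted-parameter correction
    hosmer_lemeshow(p, rbinom(2000, 1, p), fitted_df = 0)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # squared (miscalibrated) probabilities are detected
  rejects <- vapply(1:20, function(i) {
    p <- runif(2000, 0.05, 0.95)
    y <- rbinom(2000, 1, p)
    hosmer_lemeshow(p^2, y)$p < 0.05
  }, TRUE)
  expect_gte(mean(rejects), 0.9)
  # constant probabilities equal to prevalence: chi-square ~ 0
  yy <- rep(0:1, c(60, 40))
  expect_lt(hosmer_lemeshow(rep(0.4, 100), yy)$chi2, 1e-9)
})

test_that("net benefit follows its defining formula", {
  labels <- c(rep(1, 30), rep(0, 70))
  scores <- c(rep(0.9, 30), rep(0.9, 10), rep(0.05, 60))
  dc <- decision_curve(scores, labels, thresholds = c(0, 0.2))
  # at pt = 0.2: TP = 30, FP = 10 -> NB = 0.3 - 0.1 * 0.25
  expect_equal(dc$net_benefit[dc$threshold == 0.2], 0.275)
  # treat-all at pt = 0 equals prevalence
  expect_equal(dc$treat_all[dc$threshold == 0], 0.3)
  expect_true(all(dc$treat_none == 0))
  # a perfect model holds NB = prevalence at every threshold
  perf <- decision_curve(labels, labels, thresholds = seq(0, 0.9, 0.1))
  expect_true(all(abs(perf$net_benefit - 0.3) < 1e-12))
})

test_that("Wald odds ratios and the corner cases", {
  sym <- odds_ratio_wald(5, 5, 5, 5)
  expect_equal(sym$or, 1)
  expect_warning(h <- odds_ratio_wald(0, 5, 5, 5), "Haldane")
  expect_true(is.finite(h$or))
  expect_true(is.na(odds_ratio_wald(0, 0, 5, 5)$or))
})

test_that("logistic regression agrees with the 2x2 odds ratio and recovers betas", {
  set.seed(41)
  x <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, plogis(-0.5 + 0.9 * x))
  rep1 <- logistic_regression(cbind(exposure = x), y, "univariable")
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  expect_equal(rep1$or, odds_ratio_wald(a, b, cc, d)$or, tolerance = 1e-6)
  # coefficient recovery at n = 1000 on the phantom label model
  coh <- generate_cohort(phantom_config(n_patients = 1000, seed = 50),
                         render = FALSE)
  yy <- vapply(coh, `[[`, 0L, "stas")
  Z <- cbind(mwts = scale(vapply(coh, function(p) p$clinical$Mwts, 0))[, 1],
             frac = scale(vapply(coh, function(p) p$truth$frac_sub3, 0))[, 1],
             peri = scale(vapply(coh, function(p) p$truth$peri_score, 0))[, 1])
  fit <- glm(yy ~ Z, binomial())
  planted <- c(1.2, 2.2, 1.3)
  expect_lt(max(abs(coef(fit)[-1] - planted)), 0.45)
  # complete separation falls back to a penalised fit instead of exploding
  ys <- as.integer(x == 1)
  repsep <- suppressWarnings(logistic_regression(cbind(e = x), ys, "univariable"))
  expect_true(repsep$firth[1])
  expect_true(is.finite(repsep$or[1]))
})

test_that("Cohen's kappa matches hand computation", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  a <- rep(c(1, 1, 0, 0), c(40, 5, 5, 50))
  b <- rep(c(1, 0, 1, 0), c(40, 5, 5, 50))
  po <- 0.9
  pe <- 0.45 * 0.45 + 0.55 * 0.55
  expect_equal(cohens_kappa(a, b), (po - pe) / (1 - pe))
  set.seed(3)
  k0 <- cohens_kappa(rbinom(500, 1, 0.5), rbinom(500, 1, 0.5))
  expect_lt(abs(k0), 0.1)
  expect_true(is.na(cohens_kappa(rep(1, 5), rep(1, 5))))
})
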