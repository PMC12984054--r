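test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  # worked 6-case x 4-rater table; oracle computed from mean squares here
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  n <- nrow(m); k <- ncol(m)
  a <- anova(lm(c(m) ~ factor(rep(1:n, k)) + factor(rep(1:k, each = n))))
  msr <- a["factor(rep(1:n, k))", "Mean Sq"]
  msc <- a["factor(rep(1:k, each = n))", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_filter(list(f = m))$icc[["f"]]
  expect_equal(got, want, tolerance = 1e-6)

  # identical columns: ICC 1, kept; independent noise: near 0, dropped
  same <- matrix(rep(rnorm(20), 3), ncol = 3)
  set.seed(4)
  noise <- matrix(rnorm(150), ncol = 3)
  res <- icc_filter(list(stable = same, junk = noise))
  expect_equal(res$icc[["stable"]], 1, tolerance = 1e-9)
  expect_lt(res$icc[["junk"]], 0.3)
  expect_identical(res$keep, "stable")
})

test_that("the Z-score scaler is fitted on training rows only", {
  tab <- data.frame(x = c(1, 2, 3, 10), y = c(5, 5, 5, 5), z = c(0, 1, 0, 9))
  split <- c("train", "train", "train", "val")
  expect_warning(zs <- zscore_fit_apply(tab, split), "zero-variance")
  expect_false("y" %in% colnames(zs$table))
  sigma <- sd(c(1, 2, 3))
  expect_equal(zs$table$x[1:3], (c(1, 2, 3) - 2) / sigma)
  # validation row scaled with the training scaler
  expect_equal(zs$table$x[4], (10 - 2) / sigma)
  # a validation row equal to the training mean maps to zero
  expect_equal(unname(as.numeric(zs$table[1, "x"] + zs$table[3, "x"]) / 2), 0)
})

test_that("Mann-Whitney screening matches exact enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 0, 0, 1, 1, 1)
  tab <- data.frame(f = x)
  res <- mannwhitney_filter(tab, y)
  # {4,5,6} vs {1,2,3}: U = 0, two-sided exact p = 2/20
  expect_equal(unname(res$p[["f"]]), 0.1)
  expect_length(res$keep, 0)
  # perfectly separated at n = 20/20 is retained with tiny p
  tab2 <- data.frame(g = c(rnorm(20), rnorm(20) + 100))
  y2 <- rep(0:1, each = 20)
  res2 <- mannwhitney_filter(tab2, y2)
  expect_lt(res2$p[["g"]], 1e-6)
  expect_identical(res2$keep, "g")
  # feature identical across classes is never kept
  res3 <- mannwhitney_filter(data.frame(h = rep(1, 40)), y2)
  expect_length(res3$keep, 0)
  expect_error(mannwhitney_filter(tab, c(0, 0, 0, 0, 0, 1)), "at least 2")
})

test_that("Pearson pruning is greedy with the documented tie-break", {
  set.seed(21)
  n <- 50
  a <- rnorm(n)
  tab <- data.frame(a = a, b = a + rnorm(n, 0, 0.01), c = a + rnorm(n, 0, 0.02),
                    d = rnorm(n))
  y <- as.integer(a + rnorm(n) > 0)
  up <- mannwhitney_filter(tab, y)$p
  res <- pearson_prune(tab, up)
  # a, b, c are mutually correlated above 0.9: exactly one survives
  expect_length(intersect(res$keep, c("a", "b", "c")), 1L)
  expect_true("d" %in% res$keep)
  # duplicated column: one copy survives, tie broken against the later name
  tab2 <- data.frame(p = a, q = a)
  up2 <- c(p = 0.5, q = 0.5)
  expect_identical(pearson_prune(tab2, up2)$keep, "p")
  # independent noise features all survive
  set.seed(22)
  tab3 <- as.data.frame(matrix(rnorm(300), ncol = 6))
  up3 <- setNames(runif(6), colnames(tab3))
  expect_length(pearson_prune(tab3, up3)$keep, 6L)
})

test_that("mRMR ranks by relevance and penalises redundancy", {
  set.seed(31)
  n <- 400
  A <- rnorm(n)
  y <- as.integer(A > 0)           # label is a function of A
  tabl <- data.frame(A = A, B = A + rnorm(n, 0, 0.02), C = y + rnorm(n, 0, 0.8),
                     N1 = rnorm(n), N2 = rnorm(n))
  sel <- mrmr_select(tabl, y, m = 3)
  expect_identical(sel[1], "A")
  # B (a copy of A) is penalised: the informative independent C comes second
  expect_identical(sel[2], "C")
  # m = total features returns a permutation of all features
  all_sel <- mrmr_select(tabl, y, m = 5)
  expect_setequal(all_sel, colnames(tabl))
  expect_error(mrmr_select(tabl, y, m = 0), "positive")
})

test_that("LASSO selection recovers a planted support", {
  # min-deviance lambda is sensitive (keeps all signals); the 1-SE rule is
  # specific (few false positives) -- both behaviours are asserted
  hits <- 0; fp_ok <- 0
  for (s in 1:25) {
    set.seed(300 + s)
    n <- 200
    X <- matrix(rnorm(n * 23), n, 23)
    colnames(X) <- c(paste0("s", 1:3), paste0("n", 1:20))
    eta <- X[, 1] * 1.4 + X[, 2] * 1.2 - X[, 3] * 1.3
    y <- rbinom(n, 1, plogis(eta))
    res_min <- lasso_select(as.data.frame(X), y, seed = s)
    res_1se <- lasso_select(as.data.frame(X), y, seed = s, rule = "1se")
    hits <- hits + all(paste0("s", 1:3) %in% res_min$keep)
    fp_ok <- fp_ok + (sum(grepl("^n", res_1se$keep)) <= 2 &&
                        all(paste0("s", 1:3) %in% res_1se$keep))
  }
  expect_gte(hits / 25, 0.8)
  expect_gte(fp_ok / 25, 0.8)
})

test_that("the weak-penalty end of the LASSO path approaches the MLE", {
  set.seed(7)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("u", "v", "w")
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = c(0.1, 1e-5),
                        standardize = TRUE, thresh = 1e-12)
  mle <- coef(glm(y ~ X, binomial()))
  expect_lt(max(abs(as.numeric(coef(fit, s = 1e-5)) - as.numeric(mle))), 1e-3)
})

test_that("cascade stages are nested and fitted on training rows only", {
  coh <- generate_cohort(phantom_config(n_patients = 120, seed = 88),
                         render = FALSE)
  y <- vapply(coh, `[[`, 0L, "stas")
  # tabular stand-in with planted signal + noise + redundant copies
  set.seed(12)
  n <- length(y)
  sig <- vapply(coh, function(p) p$truth$frac_sub3, 0)
  X <- cbind(sig1 = sig + rnorm(n, 0, 0.05),
             sig1_copy = sig + rnorm(n, 0, 0.051),
             mw = vapply(coh, function(p) p$clinical$Mwts, 0),
             matrix(rnorm(n * 15), n, 15,
                    dimnames = list(NULL, paste0("noise", 1:15))))
  split <- split_cohort(y, seed = 3)
  rep <- suppressWarnings(
    run_selection_cascade(as.data.frame(X), y, split, seed = 5))
  st <- rep$stages
  expect_true(all(st$utest %in% st$zscore))
  expect_true(all(st$pearson %in% st$utest))
  expect_true(all(st$mrmr %in% st$pearson))
  expect_true(all(st$lasso %in% st$mrmr))
  # leakage audit: perturbing validation rows changes nothing
  X2 <- X
  X2[split == "val", ] <- X2[split == "val", ] + 100
  rep2 <- suppressWarnings(
    run_selection_cascade(as.data.frame(X2), y, split, seed = 5))
  expect_identical(rep$stages, rep2$stages)
  expect_identical(rep$lasso, rep2$lasso)
})

test_that("label permutation collapses the selected set", {
  coh <- generate_cohort(phantom_config(n_patients = 150, seed = 99),
                         render = FALSE)
  y <- vapply(coh, `[[`, 0L, "stas")
  n <- length(y)
  set.seed(14)
  sig <- vapply(coh, function(p) p$truth$frac_sub3, 0)
  X <- as.data.frame(cbind(s1 = sig + rnorm(n, 0, 0.03),
                           s2 = scale(vapply(coh, function(p) p$clinical$Mwts, 0)) +
                             rnorm(n, 0, 0.2),
                           matrix(rnorm(n * 10), n, 10,
                                  dimnames = list(NULL, paste0("x", 1:10)))))
  n_true <- length(suppressWarnings(
    run_selection_cascade(X, y, seed = 2))$final)
  perm_sizes <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    yp <- sample(y)
    length(tryCatch(
      suppressWarnings(run_selection_cascade(X, yp, seed = 2))$final,
      error = function(e) character(0)))
  }, 0)
  expect_lte(mean(perm_sizes), 0.5 * n_true)
})
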