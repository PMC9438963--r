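test_that("partial Spearman reduces to plain Spearman without covariates", {
  expect_equal(partial_spearman(1:10, (1:10)^3)$rho, 1)
  set.seed(21)
  for (k in 1:100) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(partial_spearman(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # ties handled by midranks
  x <- c(1, 1, 2, 3, 3, 4, 7, 7)
  y <- c(2, 1, 2, 5, 4, 4, 9, 8)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("covariate control matches the rank-residual oracle and absorbs shared signal", {
  set.seed(22)
  for (k in 1:50) {
    x <- rnorm(15); y <- rnorm(15); cov <- matrix(rnorm(45), 15, 3)
    expect_equal(partial_spearman(x, y, cov)$rho,
                 oracle_partial_spearman(x, y, cov), tolerance = 1e-12)
  }
  # y identical to a covariate: partial rho collapses relative to plain
  set.seed(23)
  plain <- partial <- numeric(200)
  for (k in 1:200) {
    cov <- matrix(rnorm(36), 12, 3)
    y <- cov[, 1]
    x <- rnorm(12)
    plain[k] <- abs(partial_spearman(x, y)$rho)
    partial[k] <- abs(partial_spearman(x, y, cov)$rho)
  }
  expect_lt(median(partial), median(plain))
})

test_that("degenerate correlation inputs return rho 0 with p 1", {
  expect_warning(res <- partial_spearman(rep(2, 8), rnorm(8)), "constant")
  expect_equal(res, list(rho = 0, p = 1))
  expect_error(partial_spearman(rnorm(4), rnorm(4), matrix(rnorm(8), 4, 2)),
               "n >= C \\+ 3")
})

test_that("edge selection produces disjoint sign-split masks consistent with the scalar test", {
  coh <- generate_cohort(12, 10, 3, 1, 0.5, seed = 31)
  d <- as_cohort_dataset(coh)
  sel <- select_edges(d, 0.10)
  expect_false(any(sel$positive_mask & sel$negative_mask))
  expect_true(all(sel$rho[sel$positive_mask] > 0))
  expect_true(all(sel$rho[sel$negative_mask] < 0))
  expect_true(all(sel$p[sel$positive_mask | sel$negative_mask] < 0.10))
  # per-edge agreement with the scalar partial Spearman
  for (e in c(1, 10, 25, 45)) {
    ps <- partial_spearman(d$edge_matrix[, e], d$behaviour, d$covariates)
    expect_equal(sel$rho[e], ps$rho, tolerance = 1e-12)
    expect_equal(sel$p[e], ps$p, tolerance = 1e-12)
  }
  # threshold near 1 selects every edge into one of the two masks
  sel_all <- select_edges(d, 1 - 1e-12)
  expect_equal(sum(sel_all$positive_mask) + sum(sel_all$negative_mask),
               ncol(d$edge_matrix))
})

test_that("selection type-I rate on null cohorts matches the threshold", {
  frac <- vapply(1:50, function(s) {
    coh <- generate_null_cohort(12, 10, seed = 500 + s)
    sel <- select_edges(as_cohort_dataset(coh), 0.01)
    mean(sel$positive_mask | sel$negative_mask)
  }, numeric(1))
  expect_gt(mean(frac), 0.002)
  expect_lt(mean(frac), 0.03)
})

test_that("strongly coupled edges are recovered into the positive mask", {
  # 3 planted edges at noise 0: each carries marginal rho = 1/sqrt(3),
  # individually significant at n = 60
  coh <- generate_cohort(60, 12, 3, 1, 0, seed = 32,
                         covariate_effects = c(0, 0, 0))
  sel <- select_edges(as_cohort_dataset(coh), 0.05)
  expect_true(all(sel$positive_mask[coh$truth$signal_edges + 1L]))
})

test_that("network strength is the masked sum of raw edge values", {
  expect_equal(network_strength(c(0.3, -0.1, 0.5), rep(FALSE, 3)), 0)
  expect_equal(network_strength(c(0.3, -0.1, 0.5),
                                c(TRUE, TRUE, FALSE)), 0.2)
  set.seed(33)
  v <- runif(20, -1, 1)
  a <- rbinom(20, 1, 0.3) == 1
  b <- rbinom(20, 1, 0.3) == 1 & !a
  expect_equal(network_strength(v, a | b),
               network_strength(v, a) + network_strength(v, b))
  expect_error(network_strength(1:3, c(TRUE, FALSE)), "lengths differ")
})

test_that("strength model is exact OLS with a mean fallback when degenerate", {
  s <- c(1, 2, 3, 4, 5)
  m <- fit_strength_model(s, 2 * s + 1)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_false(m$degenerate)
  # oracle equivalence: normal equations solve
  set.seed(34)
  s <- rnorm(15); y <- rnorm(15)
  m <- fit_strength_model(s, y)
  beta <- solve(crossprod(cbind(1, s)), crossprod(cbind(1, s), y))
  expect_equal(c(m$intercept, m$slope), as.numeric(beta), tolerance = 1e-10)
  # refit on own training data reproduces coefficients
  m2 <- fit_strength_model(s, y)
  expect_identical(c(m$slope, m$intercept), c(m2$slope, m2$intercept))
  # degenerate: constant strengths predict the training mean
  md <- fit_strength_model(rep(0, 10), y[1:10])
  expect_true(md$degenerate)
  expect_equal(predict_strength(md, c(-5, 0, 5)), rep(mean(y[1:10]), 3))
})

test_that("LOOCV matches an independently coded naive implementation", {
  for (s in 1:5) {
    coh <- generate_cohort(5, 5, 2, 1, 0.5, seed = 600 + s,
                           covariate_effects = c(0, 0, 0))
    d <- cohort_dataset(coh$edge_matrix, coh$behaviour)  # C = 0
    fit <- loocv_predict(d, 0.35, 0.35, quiet = TRUE)
    oracle <- oracle_loocv(coh$edge_matrix, coh$behaviour, 0.35, 0.35)
    expect_equal(unname(fit$predicted), unname(oracle$pred),
                 tolerance = 1e-10)
    expect_equal(unname(fit$rho_true), unname(oracle$rho_true),
                 tolerance = 1e-10)
  }
})

test_that("LOOCV predictions never leak the left-out subject's behaviour", {
  coh <- generate_cohort(10, 10, 2, 1, 0.5, seed = 35)
  d <- as_cohort_dataset(coh)
  fit <- loocv_predict(d, 0.1, 0.1, quiet = TRUE)
  for (i in c(1, 4, 10)) {
    beh2 <- d$behaviour
    beh2[i] <- beh2[i] + 50
    d2 <- cohort_dataset(d$edge_matrix, beh2, d$covariates)
    fit2 <- loocv_predict(d2, 0.1, 0.1, quiet = TRUE)
    expect_identical(fit2$predicted[i, ], fit$predicted[i, ])
  }
})

test_that("fold masks are disjoint and rank-based selection is scale equivariant", {
  coh <- generate_cohort(12, 12, 3, 1, 0.5, seed = 36)
  d <- as_cohort_dataset(coh)
  fit <- loocv_predict(d, 0.1, 0.1, quiet = TRUE)
  for (fm in fit$fold_masks) {
    expect_false(any(fm$positive_mask & fm$negative_mask))
  }
  d_scaled <- cohort_dataset(d$edge_matrix * 3, d$behaviour, d$covariates)
  fit_s <- loocv_predict(d_scaled, 0.1, 0.1, quiet = TRUE)
  for (k in seq_along(fit$fold_masks)) {
    expect_identical(fit_s$fold_masks[[k]]$positive_mask,
                     fit$fold_masks[[k]]$positive_mask)
    expect_identical(fit_s$fold_masks[[k]]$negative_mask,
                     fit$fold_masks[[k]]$negative_mask)
  }
  # strengths rescale linearly, so refit predictions are unchanged
  expect_equal(fit_s$predicted, fit$predicted, tolerance = 1e-8)
})

test_that("a prebuilt workspace reproduces the direct computation", {
  coh <- generate_cohort(10, 10, 2, 1, 1, seed = 37)
  d <- as_cohort_dataset(coh)
  ws <- cpmpred:::cpm_workspace(d)
  direct <- loocv_predict(d, 0.05, 0.05, quiet = TRUE)
  reused <- loocv_predict(d, 0.05, 0.05, workspace = ws, quiet = TRUE)
  expect_identical(direct$predicted, reused$predicted)
})

test_that("empty-mask folds fall back to the training mean with a warning", {
  coh <- generate_null_cohort(8, 8, seed = 38)
  d <- as_cohort_dataset(coh)
  # at an extreme threshold every fold has empty masks
  expect_warning(fit <- loocv_predict(d, 1e-8, 1e-8), "degenerate folds")
  train_means <- vapply(seq_len(8),
                        function(i) mean(d$behaviour[-i]), numeric(1))
  expect_equal(unname(fit$predicted[, "positive"]), train_means)
  expect_equal(unname(fit$predicted[, "negative"]), train_means)
  expect_equal(fit$degenerate_folds$positive, 1:8)
})
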