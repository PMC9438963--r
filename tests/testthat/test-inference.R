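test_that("the default threshold grid has 500 values with exact endpoints", {
  g <- threshold_grid()
  expect_length(g, 500)
  expect_equal(g[1], 1e-4)
  expect_equal(g[500], 0.05)
  expect_equal(diff(g), rep(1e-4, 499))
  g2 <- threshold_grid(0.001, 0.01, 0.001)
  expect_length(g2, 10)
})

test_that("threshold search returns the per-network argmax with smallest-threshold ties", {
  coh <- generate_cohort(12, 12, 3, 1, 0.5, seed = 41)
  d <- as_cohort_dataset(coh)
  grid <- threshold_grid(0.002, 0.05, 0.002)
  ts <- optimize_thresholds(d, grid)
  expect_equal(ts$chosen_p_pos,
               min(grid[ts$curves$rho_pos == max(ts$curves$rho_pos)]))
  expect_equal(ts$chosen_p_neg,
               min(grid[ts$curves$rho_neg == max(ts$curves$rho_neg)]))
  expect_equal(unname(ts$rho_at_chosen["positive"]), max(ts$curves$rho_pos))
})

test_that("the one-pass sweep equals running the full LOOCV at each threshold", {
  coh <- generate_cohort(11, 10, 2, 1, 0.8, seed = 42)
  d <- as_cohort_dataset(coh)
  grid <- threshold_grid(0.005, 0.05, 0.005)
  ts <- optimize_thresholds(d, grid)
  for (k in c(1, 4, 10)) {
    fit <- loocv_predict(d, grid[k], grid[k], quiet = TRUE)
    expect_equal(unname(fit$rho_true["positive"]), ts$curves$rho_pos[k],
                 tolerance = 1e-10)
    expect_equal(unname(fit$rho_true["negative"]), ts$curves$rho_neg[k],
                 tolerance = 1e-10)
  }
})

test_that("permutation p-values follow the add-one exceedance formula", {
  expect_equal(perm_pvalue(0.5, seq(-0.99, 0.49, length.out = 100)), 1 / 101)
  null10 <- c(rep(0.6, 10), seq(-0.9, 0.4, length.out = 90))
  expect_equal(perm_pvalue(0.5, null10), 11 / 101)
  expect_equal(perm_pvalue(-2, runif(100, -1, 1)), 101 / 101)
  expect_equal(perm_pvalue(1, rep(0, 5000)), 1 / 5001)
  # monotone non-increasing in rho_true for fixed null
  null <- rnorm(200)
  p <- vapply(seq(-1, 1, 0.1), function(r) perm_pvalue(r, null), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("permutation runs are seed-reproducible and default to 5000 replicates", {
  expect_equal(eval(formals(permutation_test)$n_permutations), 5000)
  coh <- generate_cohort(10, 10, 2, 1, 0.5, seed = 43)
  d <- as_cohort_dataset(coh)
  a <- permutation_test(d, 0.05, 0.05, n_permutations = 60, seed = 9)
  b <- permutation_test(d, 0.05, 0.05, n_permutations = 60, seed = 9)
  expect_identical(a$positive$rho_null, b$positive$rho_null)
  expect_identical(a$negative$rho_null, b$negative$rho_null)
  expect_equal(a$positive$p_permu,
               perm_pvalue(a$positive$rho_true, a$positive$rho_null))
  expect_gte(a$positive$p_permu, 1 / 61)
  expect_lte(a$positive$p_permu, 1)
  c_ <- permutation_test(d, 0.05, 0.05, n_permutations = 60, seed = 10)
  expect_false(identical(a$positive$rho_null, c_$positive$rho_null))
})

test_that("tuning on the observed data without re-tuned permutations inflates rejections", {
  # the optimism the tune-then-test procedure can introduce: on null
  # cohorts, permuting at thresholds pre-tuned on the observed data
  # rejects more often than carrying the tuning into each replicate
  grid <- threshold_grid(0.005, 0.05, 0.005)
  n_perm <- 60
  rej_off <- rej_on <- matrix(NA, 100, 2)
  for (s in 1:100) {
    coh <- generate_null_cohort(12, 15, seed = 7000 + s)
    d <- as_cohort_dataset(coh)
    ws <- cpmpred:::cpm_workspace(d)
    tune <- optimize_thresholds(d, grid, workspace = ws)
    off <- permutation_test(d, tune$chosen_p_pos, tune$chosen_p_neg,
                            n_permutations = n_perm, seed = 8000 + s,
                            reoptimize = FALSE, workspace = ws)
    on <- permutation_test(d, tune$chosen_p_pos, tune$chosen_p_neg,
                           n_permutations = n_perm, seed = 8000 + s,
                           reoptimize = TRUE, grid = grid, workspace = ws)
    rej_off[s, ] <- c(off$positive$p_permu, off$negative$p_permu) < 0.05
    rej_on[s, ] <- c(on$positive$p_permu, on$negative$p_permu) < 0.05
  }
  expect_gt(mean(rej_off), mean(rej_on))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.037), 0.037)
  set.seed(44)
  for (k in 1:200) {
    p <- runif(sample(2:20, 1))
    adj <- fdr_correct(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_correct(c(0.5, NA)), "\\[0, 1\\]")
})
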