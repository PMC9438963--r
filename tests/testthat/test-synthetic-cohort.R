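test_that("cohort dimensions, bounds and recorded truth are consistent", {
  coh <- generate_cohort(12, n_nodes = 116, n_signal_edges = 10,
                         effect_scale = 0.5, noise_sd = 1, seed = 42)
  expect_equal(dim(coh$edge_matrix), c(12, 6670))
  expect_true(all(coh$edge_matrix > -1 & coh$edge_matrix < 1))
  expect_length(coh$truth$signal_edges, 10)
  expect_false(anyDuplicated(coh$truth$signal_edges) > 0)
  expect_true(all(coh$truth$signal_edges >= 0 &
                  coh$truth$signal_edges < 6670))
  expect_equal(coh$truth$edge_effects, rep(0.5, 10))
  expect_equal(dim(coh$covariates), c(12, 3))
  expect_true(all(coh$covariates[, "sex"] %in% c(0, 1)))
})

test_that("identical seeds reproduce the cohort bit for bit", {
  a <- generate_cohort(8, 20, 3, 1, 0.5, seed = 7)
  b <- generate_cohort(8, 20, 3, 1, 0.5, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(8, 20, 3, 1, 0.5, seed = 8)
  expect_false(identical(a$edge_matrix, c$edge_matrix))
  n1 <- generate_null_cohort(12, 30, seed = 1)
  n2 <- generate_null_cohort(12, 30, seed = 1)
  expect_identical(n1$edge_matrix, n2$edge_matrix)
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(6, 10, 2, 1, 1, seed = 5))
  invisible(generate_motion_trace(50, 0.2, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("null cohorts carry no edge-behaviour association", {
  # distribution of plain Spearman between behaviour and a fixed edge over
  # many null cohorts: centred on zero, signs balanced
  rhos <- vapply(1:200, function(s) {
    coh <- generate_null_cohort(10, 10, seed = s)
    spearman_rho(coh$edge_matrix[, 7], coh$behaviour)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.08)
  expect_gt(mean(rhos > 0), 0.35)
  expect_lt(mean(rhos > 0), 0.65)
  coh <- generate_null_cohort(12, 30, seed = 1)
  expect_length(coh$truth$signal_edges, 0)
  expect_equal(coh$truth$covariate_effects, c(0, 0, 0))
})

test_that("noiseless behaviour is an exact linear function of planted edges", {
  coh <- generate_cohort(12, 20, 4, effect_scale = 1.3, noise_sd = 0,
                         seed = 11, covariate_effects = c(0, 0, 0))
  x <- coh$edge_matrix[, coh$truth$signal_edges + 1L]
  fit <- lm(coh$behaviour ~ x)
  expect_lt(max(abs(coef(fit)[-1] - coh$truth$edge_effects)), 1e-8)
  expect_lt(abs(coef(fit)[1]), 1e-8)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(generate_cohort(3, 10, 1, 1, 1, seed = 1), "n_subjects")
  expect_error(generate_cohort(10, 5, 99, 1, 1, seed = 1), "edge space")
  expect_error(generate_cohort(10, 10, 1, Inf, 1, seed = 1), "finite")
})

test_that("noise calibration hits the target population R-squared", {
  ns <- noise_sd_for_r2(10, 1, 0.5)
  # empirical check on a large cohort: R2 of behaviour on the planted edges
  coh <- generate_cohort(4000, 12, 10, 1, ns, seed = 3,
                         covariate_effects = c(0, 0, 0))
  x <- coh$edge_matrix[, coh$truth$signal_edges + 1L]
  r2 <- summary(lm(coh$behaviour ~ x))$r.squared
  expect_gt(r2, 0.45)
  expect_lt(r2, 0.55)
})

test_that("simulated time series reproduce the target correlation", {
  # independent nodes: off-diagonal sample correlations centred on zero
  ts <- generate_timeseries(155, 8, seed = 2)
  fc <- cor(ts)
  expect_lt(max(abs(fc[upper.tri(fc)])), 0.35)
  # large-sample convergence to a fixed PSD target
  r <- diag(5)
  r[1, 2] <- r[2, 1] <- 0.6
  r[3, 4] <- r[4, 3] <- -0.4
  ts <- generate_timeseries(100000, 5, r, seed = 4)
  expect_lt(max(abs(cor(ts) - r)), 0.01)
  expect_warning(generate_timeseries(10, 20, seed = 1), "rank deficient")
})

test_that("non-PSD targets are projected and flagged", {
  r <- matrix(0.9, 3, 3)
  r[1, 3] <- r[3, 1] <- -0.9   # violates PSD
  diag(r) <- 1
  ts <- generate_timeseries(5000, 3, r, seed = 6)
  expect_true(isTRUE(attr(ts, "psd_projected")))
  fc <- cor(ts)
  expect_true(all(eigen(fc, symmetric = TRUE)$values > -1e-10))
})

test_that("motion traces honour the requested spike fraction", {
  clean <- generate_motion_trace(155, 0, seed = 1)
  expect_true(all(framewise_displacement(clean) < 0.5))
  spiky <- generate_motion_trace(155, 0.5, seed = 1)
  fd <- framewise_displacement(spiky)
  expect_gt(mean(fd > 0.5), 0.35)
  expect_false(qc_subject(spiky)$passed)
  expect_true("fd_spike_fraction" %in% qc_subject(spiky)$reasons)
  expect_identical(generate_motion_trace(80, 0.1, seed = 3),
                   generate_motion_trace(80, 0.1, seed = 3))
})

test_that("cohorts survive the CSV/JSON round trip", {
  coh <- generate_cohort(6, 10, 2, 1, 0.5, seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("edges.csv", "pheno.csv", "truth.json")))))
  back <- read_cohort(dir)
  expect_equal(back$edge_matrix, coh$edge_matrix, tolerance = 1e-12)
  expect_equal(back$behaviour, coh$behaviour, tolerance = 1e-12)
  expect_equal(back$truth$signal_edges, coh$truth$signal_edges)
  # header uses the canonical i_j edge ids
  hdr <- names(read.csv(file.path(dir, "edges.csv"), check.names = FALSE))
  expect_equal(hdr[2:4], c("0_1", "0_2", "0_3"))
})
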