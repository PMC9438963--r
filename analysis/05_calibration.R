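#!/usr/bin/env Rscript
# Statistical behaviour of the inference machinery on null cohorts:
# (i) calibration of the permutation test at fixed selection thresholds,
# (ii) the optimism introduced when thresholds are tuned on the observed
# data but the permutation replicates are not re-tuned. Writes
# results/calibration.csv.
#
# Scaled for a desk run (50 cohorts, 100 permutations); the test suite
# runs the larger 200 x 200 version.

suppressPackageStartupMessages(library(cpmpred))
dir.create("results", showWarnings = FALSE)

n_cohorts <- 50
grid <- threshold_grid(0.005, 0.05, 0.005)
fixed <- tuned_off <- tuned_on <- matrix(NA, n_cohorts, 2)

for (s in seq_len(n_cohorts)) {
  coh <- generate_null_cohort(12, 20, seed = 100 + s)
  d <- as_cohort_dataset(coh)
  ws <- cpmpred:::cpm_workspace(d)
  # fixed a-priori thresholds: the exchangeable, calibrated case
  pm <- permutation_test(d, 0.01, 0.01, n_permutations = 100,
                         seed = 200 + s, workspace = ws)
  fixed[s, ] <- c(pm$positive$p_permu, pm$negative$p_permu) < 0.05
  # thresholds tuned on the observed data
  tune <- optimize_thresholds(d, grid, workspace = ws)
  off <- permutation_test(d, tune$chosen_p_pos, tune$chosen_p_neg,
                          n_permutations = 100, seed = 300 + s,
                          reoptimize = FALSE, workspace = ws)
  on <- permutation_test(d, tune$chosen_p_pos, tune$chosen_p_neg,
                         n_permutations = 100, seed = 300 + s,
                         reoptimize = TRUE, grid = grid, workspace = ws)
  tuned_off[s, ] <- c(off$positive$p_permu, off$negative$p_permu) < 0.05
  tuned_on[s, ] <- c(on$positive$p_permu, on$negative$p_permu) < 0.05
}

tab <- data.frame(
  procedure = c("fixed thresholds",
                "tuned thresholds, replicates not re-tuned",
                "tuned thresholds, replicates re-tuned"),
  rejection_rate = c(mean(fixed), mean(tuned_off), mean(tuned_on)))
write.csv(tab, "results/calibration.csv", row.names = FALSE)
cat("Null rejection rates at alpha = 0.05 over", n_cohorts, "cohorts:\n")
print(tab, row.names = FALSE)
cat("\nTuning on the observed data without re-tuning the replicates\n",
    "inflates the rejection rate; re-tuning restores calibration.\n")
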