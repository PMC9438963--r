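#!/usr/bin/env Rscript
# Simulate the study cohort: 12 subjects with AAL-116 connectomes (6670
# edges) and processing-speed scores at three timepoints. The 1-month
# change score is coupled to 3 planted edges, the 6-month score to 2
# independent planted edges; one subject is missing each follow-up score,
# mirroring the per-contrast dropout pattern of small surgical cohorts.
# Writes results/study_inputs/{edges.csv,behaviour.csv,truth_*.json}.

suppressPackageStartupMessages(library(cpmpred))
out <- "results/study_inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

coh <- generate_cohort(12, n_nodes = 116, n_signal_edges = 3,
                       effect_scale = 1.5, noise_sd = 0.3, seed = seed,
                       covariate_effects = c(0, 0, 0))
second <- plant_behaviour(coh, n_signal_edges = 2, effect_scale = 1.5,
                          noise_sd = 0.3, seed = seed + 1)

edges <- as.data.frame(coh$edge_matrix)
names(edges) <- edge_ids(116)
write.csv(cbind(subject_id = coh$subject_ids, edges),
          file.path(out, "edges.csv"), row.names = FALSE)

# baseline processing speed: mean 116.5, sd 30.4, as in small adult cohorts
set.seed(seed)
ps_t0 <- round(116.5 + 30.4 * scale(rnorm(12))[, 1])
ps_t1 <- ps_t0 + round(10 * coh$behaviour, 1)    # 1-month change
ps_t2 <- ps_t0 + round(10 * second$behaviour, 1) # 6-month change
ps_t1[2] <- NA                                   # missing follow-up scores
ps_t2[5] <- NA
write.csv(data.frame(subject_id = coh$subject_ids,
                     ps_t0 = ps_t0, ps_t1 = ps_t1, ps_t2 = ps_t2,
                     age = round(coh$covariates[, "age"], 1),
                     sex = coh$covariates[, "sex"],
                     education = round(coh$covariates[, "education"], 1)),
          file.path(out, "behaviour.csv"), row.names = FALSE)

jsonlite::write_json(list(delta_t1 = coh$truth, delta_t2 = second$truth),
                     file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)

cat("Simulated cohort: 12 subjects x", ncol(coh$edge_matrix), "edges\n")
cat("Planted edges (delta_t1):",
    paste(coh$truth$signal_edges, collapse = ", "), "\n")
cat("Planted edges (delta_t2):",
    paste(second$truth$signal_edges, collapse = ", "), "\n")
cat("Inputs written under", out, "\n")
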