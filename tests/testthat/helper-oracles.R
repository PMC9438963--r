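# Independent brute-force oracles, coded naively on purpose: these never
# share code with the package internals they check.

# Spearman by definition: midranks, then the Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Partial Spearman via lm residuals on ranked covariates.
oracle_partial_spearman <- function(x, y, cov) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rc <- apply(as.matrix(cov), 2, rank, ties.method = "average")
  stats::cor(stats::resid(stats::lm(rx ~ rc)),
             stats::resid(stats::lm(ry ~ rc)))
}

# Full LOOCV CPM with nested loops, no covariates, edge-by-edge selection,
# lm() fits. Mirrors the procedure from its verbal description only.
oracle_loocv <- function(edge_matrix, behaviour, p_pos, p_neg) {
  n <- nrow(edge_matrix)
  ne <- ncol(edge_matrix)
  pred <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    y <- behaviour[tr]
    rho <- numeric(ne)
    pv <- numeric(ne)
    for (e in seq_len(ne)) {
      xv <- edge_matrix[tr, e]
      if (stats::sd(xv) == 0 || stats::sd(y) == 0) {
        rho[e] <- 0; pv[e] <- 1; next
      }
      r <- oracle_spearman(xv, y)
      df <- length(tr) - 2
      if (abs(r) >= 1) { pv[e] <- 0 } else {
        tt <- abs(r) * sqrt(df / (1 - r^2))
        pv[e] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
      }
      rho[e] <- r
    }
    for (sgn in 1:2) {
      sel <- if (sgn == 1) which(rho > 0 & pv < p_pos)
             else which(rho < 0 & pv < p_neg)
      s_tr <- vapply(tr, function(j) sum(edge_matrix[j, sel]), numeric(1))
      if (length(sel) == 0 || stats::var(s_tr) == 0) {
        pred[i, sgn] <- mean(y)
        next
      }
      fit <- stats::lm(y ~ s_tr)
      pred[i, sgn] <- sum(stats::coef(fit) * c(1, sum(edge_matrix[i, sel])))
    }
  }
  list(pred = pred,
       rho_true = c(positive = oracle_spearman(pred[, 1], behaviour),
                    negative = oracle_spearman(pred[, 2], behaviour)))
}

# Benjamini-Hochberg step-up by definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(scaled[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Write a small two-contrast study (edges + 3-timepoint behaviour CSVs)
# into dir; returns the paths. One subject is missing ps_t1 and one ps_t2,
# so the contrasts have n-1 complete subjects each.
make_study_inputs <- function(dir, n = 12, nodes = 15, seed = 7) {
  coh <- generate_cohort(n, nodes, n_signal_edges = 3, effect_scale = 1.5,
                         noise_sd = 0.3, seed = seed,
                         covariate_effects = c(0, 0, 0))
  second <- plant_behaviour(coh, n_signal_edges = 2, effect_scale = 1.5,
                            noise_sd = 0.3, seed = seed + 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- as.data.frame(coh$edge_matrix)
  names(edges) <- edge_ids(nodes)
  edges <- cbind(subject_id = coh$subject_ids, edges)
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  ps_t0 <- 100 + seq_len(n)          # deterministic baseline scores
  ps_t1 <- ps_t0 + coh$behaviour
  ps_t2 <- ps_t0 + second$behaviour
  ps_t1[2] <- NA
  ps_t2[5] <- NA
  beh <- data.frame(subject_id = coh$subject_ids,
                    ps_t0 = ps_t0, ps_t1 = ps_t1, ps_t2 = ps_t2,
                    age = coh$covariates[, "age"],
                    sex = coh$covariates[, "sex"],
                    education = coh$covariates[, "education"])
  write.csv(beh, file.path(dir, "behaviour.csv"), row.names = FALSE)
  list(edges = file.path(dir, "edges.csv"),
       behaviour = file.path(dir, "behaviour.csv"),
       cohort = coh, second = second)
}
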