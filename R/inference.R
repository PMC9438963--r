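#' Selection-threshold grid
#'
#' The candidate p-value thresholds swept when tuning the edge-selection
#' threshold: an inclusive arithmetic grid, by default 0.0001 to 0.05 in
#' steps of 0.0001 (500 values). The grid is generated from integer
#' multiples of the step so no endpoint is lost to floating accumulation.
#'
#' @param start,stop,step grid limits (inclusive) and spacing.
#' @return numeric vector of thresholds, ascending.
#' @examples
#' length(threshold_grid())  # 500
#' @export
threshold_grid <- function(start = 1e-4, stop = 0.05, step = 1e-4) {
  stopifnot(start > 0, stop < 1, step > 0, stop >= start)
  k0 <- round(start / step)
  k1 <- round(stop / step)
  step * (k0:k1)
}

# Threshold sweep over a prebuilt workspace: one pass computes the LOOCV
# rho_true of both networks at every candidate threshold. Per fold the
# per-edge stats are computed once; edges are ordered by p within sign and
# training/test strengths for all mask sizes come from cumulative sums, so
# the sweep costs one LOOCV plus O(E log E) per fold instead of one LOOCV
# per grid point. Numerically equivalent to calling loocv_predict at each
# grid value.
sweep_engine <- function(ws, behaviour, thresholds) {
  n <- ws$n
  tn <- length(thresholds)
  pred_pos <- matrix(NA_real_, n, tn)
  pred_neg <- matrix(NA_real_, n, tn)
  for (i in seq_len(n)) {
    f <- ws$folds[[i]]
    y_tr <- behaviour[f$train]
    my <- mean(y_tr)
    yc <- y_tr - my
    st <- edge_stats_resid(f$rx_res, f$norms, f$q, y_tr, f$df)
    for (sign in c("pos", "neg")) {
      idx <- if (sign == "pos") which(st$rho > 0) else which(st$rho < 0)
      ord <- idx[order(st$p[idx])]
      p_sorted <- st$p[ord]
      # mask size at each threshold (strict p < t)
      k_at <- findInterval(thresholds, p_sorted, left.open = TRUE)
      uk <- unique(k_at)
      # cumulative strengths over the p-ordered edges
      e_tr <- f$edges_train[, ord, drop = FALSE]
      s_cum_tr <- cbind(0, t(apply(e_tr, 1, cumsum)))
      s_cum_te <- c(0, cumsum(f$edges_test[ord]))
      pred_k <- vapply(uk, function(k) {
        s <- s_cum_tr[, k + 1]
        fit <- ols_strength(s, y_tr)
        if (fit$degenerate) fit$intercept
        else fit$intercept + fit$slope * s_cum_te[k + 1]
      }, numeric(1))
      pr <- pred_k[match(k_at, uk)]
      if (sign == "pos") pred_pos[i, ] <- pr else pred_neg[i, ] <- pr
    }
  }
  rho_pos <- vapply(seq_len(tn),
                    function(t) spearman_rho(pred_pos[, t], behaviour),
                    numeric(1))
  rho_neg <- vapply(seq_len(tn),
                    function(t) spearman_rho(pred_neg[, t], behaviour),
                    numeric(1))
  list(rho_pos = rho_pos, rho_neg = rho_neg,
       pred_pos = pred_pos, pred_neg = pred_neg)
}

#' Tune the edge-selection thresholds by grid search
#'
#' Runs the full leave-one-out CPM at every threshold of the grid and
#' records each network's cross-validated accuracy curve
#' (threshold -> rho_true). The chosen threshold per network is the argmax
#' of its own curve; exact ties break to the smallest threshold. One sweep
#' serves both networks because they never interact within a run.
#'
#' Note that thresholds tuned this way are chosen on the observed data;
#' the permutation test offers `reoptimize = TRUE` to carry the same
#' search into every null replicate (see [permutation_test()]).
#'
#' @param data a [cohort_dataset()].
#' @param grid numeric vector of candidate thresholds, ascending
#'   (default [threshold_grid()]).
#' @param workspace optional prebuilt workspace.
#' @return an object of class `"threshold_search"`: list with `curves`
#'   (data.frame: threshold, rho_pos, rho_neg), `chosen_p_pos`,
#'   `chosen_p_neg`, `rho_at_chosen` (named length-2).
#' @export
optimize_thresholds <- function(data, grid = threshold_grid(),
                                workspace = NULL) {
  stopifnot(inherits(data, "cohort_dataset"),
            all(grid > 0), all(grid < 1), !is.unsorted(grid))
  if (is.null(workspace)) workspace <- cpm_workspace(data)
  sw <- sweep_engine(workspace, data$behaviour, grid)
  if (all(is.na(sw$rho_pos)) && all(is.na(sw$rho_neg))) {
    stop("threshold search failed: every fold degenerate at every threshold")
  }
  ipos <- which.max(sw$rho_pos)   # first max == smallest threshold on ties
  ineg <- which.max(sw$rho_neg)
  structure(list(
    curves = data.frame(threshold = grid, rho_pos = sw$rho_pos,
                        rho_neg = sw$rho_neg),
    chosen_p_pos = grid[ipos],
    chosen_p_neg = grid[ineg],
    rho_at_chosen = c(positive = sw$rho_pos[ipos],
                      negative = sw$rho_neg[ineg])
  ), class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf(
    "Threshold search over %d candidates\n  positive: p < %.4g (rho_true %.3f)\n  negative: p < %.4g (rho_true %.3f)\n",
    nrow(x$curves), x$chosen_p_pos, x$rho_at_chosen["positive"],
    x$chosen_p_neg, x$rho_at_chosen["negative"]))
  invisible(x)
}

#' Permutation p-value of a cross-validated correlation
#'
#' `p = (#\{rho_null >= rho_true\} + 1) / (N + 1)` — the add-one permutation
#' p-value, bounded below by `1 / (N + 1)` (1/5001 at the default 5000
#' permutations).
#'
#' @param rho_true observed statistic.
#' @param rho_null numeric vector of permutation-null statistics.
#' @return a single p-value in `[1/(N+1), 1]`.
#' @export
perm_pvalue <- function(rho_true, rho_null) {
  (sum(rho_null >= rho_true) + 1) / (length(rho_null) + 1)
}

#' Permutation significance test for CPM accuracy
#'
#' Because leave-one-out folds are not independent, the significance of
#' `rho_true` is assessed by permutation: the behaviour scores are randomly
#' reshuffled across subjects (covariates stay attached to their subjects'
#' connectomes) and the whole cross-validated CPM is rerun on each
#' replicate. With `reoptimize = FALSE` (default) replicates are evaluated
#' at the supplied thresholds; with `reoptimize = TRUE` the threshold grid
#' search is repeated inside every replicate and the replicate's statistic
#' is its own tuned maximum — the honest null when the observed thresholds
#' were themselves tuned.
#'
#' @param data a [cohort_dataset()].
#' @param p_thr_pos,p_thr_neg thresholds at which the observed statistic is
#'   computed (and the replicates, unless `reoptimize`).
#' @param n_permutations number of replicates (default 5000).
#' @param seed integer seed; identical seeds give identical null lists.
#' @param reoptimize rerun the threshold search inside each replicate.
#' @param grid threshold grid used when `reoptimize = TRUE`.
#' @param workspace optional prebuilt workspace.
#' @return a list of class `"cpm_permutation"` with one element per network
#'   (`positive`, `negative`), each holding `rho_true`, `rho_null`,
#'   `p_permu`, `n_permutations`, `seed`; plus `thresholds` and
#'   `reoptimize`.
#' @export
permutation_test <- function(data, p_thr_pos, p_thr_neg,
                             n_permutations = 5000, seed = 1,
                             reoptimize = FALSE, grid = threshold_grid(),
                             workspace = NULL) {
  stopifnot(inherits(data, "cohort_dataset"), n_permutations >= 1)
  if (is.null(workspace)) workspace <- cpm_workspace(data)
  obs <- loocv_engine(workspace, data$behaviour, p_thr_pos, p_thr_neg)
  n <- workspace$n
  null_pos <- numeric(n_permutations)
  null_neg <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      y_perm <- data$behaviour[sample.int(n)]
      if (reoptimize) {
        sw <- sweep_engine(workspace, y_perm, grid)
        null_pos[b] <- max(sw$rho_pos)
        null_neg[b] <- max(sw$rho_neg)
      } else {
        r <- loocv_engine(workspace, y_perm, p_thr_pos, p_thr_neg)
        null_pos[b] <- r$rho_true["positive"]
        null_neg[b] <- r$rho_true["negative"]
      }
    }
  })
  structure(list(
    positive = list(rho_true = unname(obs$rho_true["positive"]),
                    rho_null = null_pos,
                    p_permu = perm_pvalue(obs$rho_true["positive"], null_pos),
                    n_permutations = n_permutations, seed = as.integer(seed)),
    negative = list(rho_true = unname(obs$rho_true["negative"]),
                    rho_null = null_neg,
                    p_permu = perm_pvalue(obs$rho_true["negative"], null_neg),
                    n_permutations = n_permutations, seed = as.integer(seed)),
    thresholds = c(positive = p_thr_pos, negative = p_thr_neg),
    reoptimize = reoptimize
  ), class = "cpm_permutation")
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%d replicates, reoptimize %s)\n  positive: rho_true %.3f, p_permu %.4f\n  negative: rho_true %.3f, p_permu %.4f\n",
    x$positive$n_permutations, if (x$reoptimize) "on" else "off",
    x$positive$rho_true, x$positive$p_permu,
    x$negative$rho_true, x$negative$p_permu))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment of a family of p-values (a thin validated front
#' end to `stats::p.adjust(method = "BH")`). Adjusted values are monotone
#' in the input order statistics and capped at 1; every adjusted value is
#' at least its raw value.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as the input.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_correct <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}
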