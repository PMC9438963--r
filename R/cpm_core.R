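#' Assemble a cohort dataset for CPM
#'
#' Bundles aligned per-subject edge vectors, a behaviour change score and
#' nuisance covariates into the container every estimator in the package
#' consumes. Missing values are not allowed: subjects with a missing
#' behaviour score must be dropped per contrast before construction
#' (listwise exclusion).
#'
#' @param edge_matrix numeric n x E matrix of connectome edges in canonical
#'   order (see [edge_index_table()]).
#' @param behaviour numeric length-n behaviour (change) score.
#' @param covariates optional numeric n x C matrix of nuisance covariates
#'   (e.g. age, sex, education); may be `NULL` for no covariate control.
#' @param subject_ids optional character ids; defaults to `S001...`.
#' @return an object of class `"cohort_dataset"`.
#' @export
cohort_dataset <- function(edge_matrix, behaviour, covariates = NULL,
                           subject_ids = NULL) {
  edge_matrix <- as.matrix(edge_matrix)
  behaviour <- as.numeric(behaviour)
  n <- nrow(edge_matrix)
  if (length(behaviour) != n) stop("behaviour length must match subjects")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match subjects")
  }
  if (anyNA(edge_matrix) || anyNA(behaviour) ||
      (!is.null(covariates) && anyNA(covariates))) {
    stop("cohort dataset must not contain missing values")
  }
  if (n < 4) stop("need at least 4 subjects, got ", n)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  structure(list(subject_ids = as.character(subject_ids),
                 edge_matrix = edge_matrix,
                 behaviour = behaviour,
                 covariates = covariates),
            class = "cohort_dataset")
}

#' @rdname cohort_dataset
#' @param cohort a `"synthetic_cohort"` from [generate_cohort()].
#' @param use_covariates include the cohort's age/sex/education as nuisance
#'   covariates (default `TRUE`).
#' @export
as_cohort_dataset <- function(cohort, use_covariates = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort_dataset(cohort$edge_matrix, cohort$behaviour,
                 covariates = if (use_covariates) cohort$covariates,
                 subject_ids = cohort$subject_ids)
}

# Columnwise midranks (average ranks for ties).
rank_cols <- function(m) {
  apply(m, 2, rank, ties.method = "average")
}

# Orthonormal basis of the column space of [1, covariates-as-ranks];
# projecting out this space implements rank-based covariate control
# (plain centering when there are no covariates).
rank_design_q <- function(covariates, n) {
  x <- if (is.null(covariates) || ncol(as.matrix(covariates)) == 0) {
    matrix(1, n, 1)
  } else {
    cbind(1, rank_cols(as.matrix(covariates)))
  }
  qr.Q(qr(x))
}

# p-value of a (partial) correlation from the t distribution with df
# degrees of freedom.
cor_pvalue <- function(rho, df) {
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(1, length(rho))
  ok <- abs(rho) < 1
  tt <- abs(rho[ok]) * sqrt(df / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  p
}

#' Partial Spearman correlation with covariate control
#'
#' Rank-transforms `x`, `y` and each covariate (average ranks for ties),
#' regresses the ranked `x` and `y` on the ranked covariates (plus an
#' intercept), and returns the Pearson correlation of the two residual
#' vectors — the standard construction of a partial Spearman correlation.
#' With no covariates this reduces exactly to the plain Spearman
#' correlation. The two-sided p-value uses the t distribution with
#' `n - C - 2` degrees of freedom.
#'
#' A constant `x` or `y` has no defined correlation; the function returns
#' `rho = 0`, `p = 1` with a warning, so such an edge is never selected.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates optional numeric n x C matrix.
#' @return a list with elements `rho` and `p`.
#' @examples
#' partial_spearman(1:10, (1:10)^2)$rho   # 1: monotone
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (anyNA(x) || anyNA(y)) stop("x and y must be finite")
  cc <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < cc + 3) stop("need n >= C + 3 observations, got n = ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: partial Spearman undefined, returning rho = 0")
    return(list(rho = 0, p = 1))
  }
  q <- rank_design_q(covariates, n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  xres <- rx - drop(q %*% crossprod(q, rx))
  yres <- ry - drop(q %*% crossprod(q, ry))
  den <- sqrt(sum(xres^2) * sum(yres^2))
  if (den == 0) {
    warning("ranks fully explained by covariates, returning rho = 0")
    return(list(rho = 0, p = 1))
  }
  rho <- sum(xres * yres) / den
  list(rho = rho, p = cor_pvalue(rho, n - cc - 2)[1])
}

# Vectorized per-edge partial Spearman against one behaviour vector.
# rx_res: pre-residualized ranked edge matrix (n x E); norms: its column
# norms; q: design basis; df: n - C - 2. Returns list(rho, p).
edge_stats_resid <- function(rx_res, norms, q, y, df) {
  ry <- rank(y, ties.method = "average")
  yres <- ry - drop(q %*% crossprod(q, ry))
  ynorm <- sqrt(sum(yres^2))
  e <- length(norms)
  if (ynorm == 0) return(list(rho = rep(0, e), p = rep(1, e)))
  den <- norms * ynorm
  rho <- as.numeric(crossprod(rx_res, yres))
  rho <- ifelse(den > 0, rho / ifelse(den > 0, den, 1), 0)
  p <- cor_pvalue(rho, df)
  p[den == 0] <- 1
  list(rho = rho, p = p)
}

# Precompute rank/residual structure for one subject set.
edge_stats_precompute <- function(edge_matrix, covariates) {
  n <- nrow(edge_matrix)
  cc <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  q <- rank_design_q(covariates, n)
  rx <- rank_cols(edge_matrix)
  rx_res <- rx - q %*% crossprod(q, rx)
  list(q = q, rx_res = rx_res, norms = sqrt(colSums(rx_res^2)),
       df = n - cc - 2)
}

#' Select positively and negatively correlated edges
#'
#' Runs the covariate-controlled partial Spearman test of every edge
#' against the behaviour score and splits the edges passing the p-value
#' threshold by the sign of their correlation. Selection is strict
#' (`p < p_threshold`); the two masks are disjoint by construction.
#'
#' @param data a [cohort_dataset()].
#' @param p_threshold selection threshold in (0, 1).
#' @return an object of class `"selection_masks"`: list with `p_threshold`,
#'   logical `positive_mask` and `negative_mask` (length E), and the
#'   per-edge `rho` and `p` vectors.
#' @export
select_edges <- function(data, p_threshold) {
  stopifnot(inherits(data, "cohort_dataset"),
            p_threshold > 0, p_threshold < 1)
  pre <- edge_stats_precompute(data$edge_matrix, data$covariates)
  st <- edge_stats_resid(pre$rx_res, pre$norms, pre$q, data$behaviour, pre$df)
  structure(list(p_threshold = p_threshold,
                 positive_mask = st$rho > 0 & st$p < p_threshold,
                 negative_mask = st$rho < 0 & st$p < p_threshold,
                 rho = st$rho, p = st$p),
            class = "selection_masks")
}

#' Network strength of a subject
#'
#' The network strength score of a subject for a selected edge set is the
#' plain sum of the subject's raw edge values over the mask; an empty mask
#' gives strength 0.
#'
#' @param edges numeric length-E edge vector for one subject.
#' @param mask logical length-E selection mask.
#' @return a single number.
#' @export
network_strength <- function(edges, mask) {
  if (length(edges) != length(mask)) {
    stop("edge vector and mask lengths differ (", length(edges), " vs ",
         length(mask), ")")
  }
  sum(edges[mask])
}

# OLS of behaviour on strength, closed form. Degenerate (constant
# strengths, e.g. empty mask) falls back to predicting the training mean.
ols_strength <- function(strengths, behaviour) {
  ms <- mean(strengths); my <- mean(behaviour)
  sc <- strengths - ms
  sxx <- sum(sc^2)
  if (sxx <= 0) {
    return(list(slope = 0, intercept = my, degenerate = TRUE))
  }
  slope <- sum(sc * (behaviour - my)) / sxx
  list(slope = slope, intercept = my - slope * ms, degenerate = FALSE)
}

#' Fit the strength-to-behaviour linear model
#'
#' Ordinary least squares of the behaviour score on a network strength
#' score, giving the slope and intercept used to predict the left-out
#' subject. Constant strengths (an empty or degenerate mask) yield a
#' degenerate model whose prediction is the training-behaviour mean, the
#' no-information optimum for squared error.
#'
#' @param strengths numeric training network strengths (length >= 3).
#' @param behaviour numeric training behaviour scores.
#' @param network_sign `"positive"` or `"negative"` label, carried through.
#' @return an object of class `"strength_model"`: list with `slope`,
#'   `intercept`, `degenerate`, `network_sign`.
#' @export
fit_strength_model <- function(strengths, behaviour,
                               network_sign = c("positive", "negative")) {
  network_sign <- match.arg(network_sign)
  stopifnot(length(strengths) == length(behaviour), length(strengths) >= 3)
  fit <- ols_strength(as.numeric(strengths), as.numeric(behaviour))
  structure(c(fit, list(network_sign = network_sign)),
            class = "strength_model")
}

#' @rdname fit_strength_model
#' @param model a `"strength_model"`.
#' @param new_strengths strengths of new subjects.
#' @export
predict_strength <- function(model, new_strengths) {
  stopifnot(inherits(model, "strength_model"))
  if (model$degenerate) {
    rep(model$intercept, length(new_strengths))
  } else {
    model$intercept + model$slope * as.numeric(new_strengths)
  }
}

#' Spearman correlation robust to constant input
#'
#' Plain Spearman correlation (Pearson on midranks) used as the
#' cross-validated accuracy statistic. A constant vector has no defined
#' rank correlation; by package convention the statistic is then 0, which
#' keeps the permutation-test statistic total and deterministic.
#'
#' @param a,b numeric vectors of equal length.
#' @return a single number in \code{[-1, 1]}.
#' @export
spearman_rho <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"))
}

# Per-fold precomputation reused across thresholds and permutations: the
# covariate-residualized ranked edge matrices do not depend on behaviour,
# so a workspace built once serves the threshold sweep and every
# permutation replicate.
cpm_workspace <- function(data) {
  stopifnot(inherits(data, "cohort_dataset"))
  n <- nrow(data$edge_matrix)
  folds <- lapply(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    pre <- edge_stats_precompute(
      data$edge_matrix[train, , drop = FALSE],
      if (is.null(data$covariates)) NULL
      else data$covariates[train, , drop = FALSE])
    c(pre, list(train = train, test = i,
                edges_train = data$edge_matrix[train, , drop = FALSE],
                edges_test = data$edge_matrix[i, ]))
  })
  structure(list(folds = folds, n = n, E = ncol(data$edge_matrix)),
            class = "cpm_workspace")
}

# Minimal LOOCV at fixed thresholds over a prebuilt workspace and an
# arbitrary behaviour vector; returns just what the permutation loop needs.
loocv_engine <- function(ws, behaviour, p_thr_pos, p_thr_neg,
                         keep_details = FALSE) {
  n <- ws$n
  pred <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("positive", "negative")))
  details <- if (keep_details) vector("list", n)
  for (i in seq_len(n)) {
    f <- ws$folds[[i]]
    y_tr <- behaviour[f$train]
    st <- edge_stats_resid(f$rx_res, f$norms, f$q, y_tr, f$df)
    mask_pos <- st$rho > 0 & st$p < p_thr_pos
    mask_neg <- st$rho < 0 & st$p < p_thr_neg
    s_tr_pos <- if (any(mask_pos))
      rowSums(f$edges_train[, mask_pos, drop = FALSE]) else numeric(length(y_tr))
    s_tr_neg <- if (any(mask_neg))
      rowSums(f$edges_train[, mask_neg, drop = FALSE]) else numeric(length(y_tr))
    fit_pos <- ols_strength(s_tr_pos, y_tr)
    fit_neg <- ols_strength(s_tr_neg, y_tr)
    s_te_pos <- sum(f$edges_test[mask_pos])
    s_te_neg <- sum(f$edges_test[mask_neg])
    pred[i, 1] <- if (fit_pos$degenerate) fit_pos$intercept
                  else fit_pos$intercept + fit_pos$slope * s_te_pos
    pred[i, 2] <- if (fit_neg$degenerate) fit_neg$intercept
                  else fit_neg$intercept + fit_neg$slope * s_te_neg
    if (keep_details) {
      details[[i]] <- list(
        masks = structure(list(p_threshold = c(positive = p_thr_pos,
                                               negative = p_thr_neg),
                               positive_mask = mask_pos,
                               negative_mask = mask_neg,
                               rho = st$rho, p = st$p),
                          class = "selection_masks"),
        models = list(
          positive = structure(c(fit_pos, list(network_sign = "positive")),
                               class = "strength_model"),
          negative = structure(c(fit_neg, list(network_sign = "negative")),
                               class = "strength_model")))
    }
  }
  rho_true <- c(positive = spearman_rho(pred[, 1], behaviour),
                negative = spearman_rho(pred[, 2], behaviour))
  list(predicted = pred, rho_true = rho_true, details = details)
}

#' Leave-one-out cross-validated CPM prediction
#'
#' For every fold, edge selection, strength computation and model fitting
#' use only the `n - 1` training subjects; the left-out subject's positive
#' and negative network strengths are computed with the training masks and
#' fed through the training models to produce its prediction. After all
#' folds, the accuracy statistic `rho_true` per network is the Spearman
#' correlation between the cross-validated predictions and the observed
#' behaviour.
#'
#' Folds in which a mask is empty (or strengths are constant) predict the
#' training-behaviour mean for that network; a warning summarizes such
#' folds unless `quiet = TRUE`.
#'
#' @param data a [cohort_dataset()].
#' @param p_thr_pos,p_thr_neg selection thresholds in (0, 1) for the
#'   positive and negative network.
#' @param workspace optional precomputed internal workspace (reused by the
#'   threshold sweep and permutation test); built on the fly if `NULL`.
#' @param quiet suppress the degenerate-fold warning.
#' @return an object of class `"cpm_loocv"`: list with `predicted` (n x 2
#'   matrix, columns positive/negative), `observed`, `rho_true` (named
#'   length-2), `thresholds`, `fold_masks`, `fold_models`,
#'   `degenerate_folds` (per sign, fold indices that fell back to the
#'   training mean).
#' @export
loocv_predict <- function(data, p_thr_pos, p_thr_neg, workspace = NULL,
                          quiet = FALSE) {
  stopifnot(inherits(data, "cohort_dataset"),
            p_thr_pos > 0, p_thr_pos < 1, p_thr_neg > 0, p_thr_neg < 1)
  if (is.null(workspace)) workspace <- cpm_workspace(data)
  res <- loocv_engine(workspace, data$behaviour, p_thr_pos, p_thr_neg,
                      keep_details = TRUE)
  deg_pos <- which(vapply(res$details,
                          function(d) d$models$positive$degenerate, logical(1)))
  deg_neg <- which(vapply(res$details,
                          function(d) d$models$negative$degenerate, logical(1)))
  if (!quiet && (length(deg_pos) > 0 || length(deg_neg) > 0)) {
    warning(sprintf(
      "degenerate folds fell back to the training mean (positive: %d, negative: %d of %d folds)",
      length(deg_pos), length(deg_neg), workspace$n), call. = FALSE)
  }
  structure(list(
    predicted = res$predicted,
    observed = data$behaviour,
    rho_true = res$rho_true,
    thresholds = c(positive = p_thr_pos, negative = p_thr_neg),
    fold_masks = lapply(res$details, `[[`, "masks"),
    fold_models = lapply(res$details, `[[`, "models"),
    degenerate_folds = list(positive = deg_pos, negative = deg_neg)
  ), class = "cpm_loocv")
}

#' @export
print.cpm_loocv <- function(x, ...) {
  cat(sprintf(
    "CPM LOOCV over %d subjects | thresholds p_pos < %.4g, p_neg < %.4g\n",
    length(x$observed), x$thresholds["positive"], x$thresholds["negative"]))
  cat(sprintf("  rho_true: positive %.3f, negative %.3f\n",
              x$rho_true["positive"], x$rho_true["negative"]))
  invisible(x)
}
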