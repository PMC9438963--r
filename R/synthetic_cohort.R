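# Edge null distribution: edges are tanh(z), z ~ N(EDGE_MU, EDGE_SD^2).
# Near-zero-mean, bounded in (-1, 1), emulating post-global-signal-regression
# resting-state correlations. Fixed package-wide; tests never depend on the
# tails.
EDGE_MU <- 0.1
EDGE_SD <- 0.4

# Run code under a caller-isolated RNG stream; the global .Random.seed is
# restored on exit so no call leaks RNG state.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Moments of the tanh-Gaussian edge distribution, by numerical quadrature.
tanh_edge_moments <- function(mu = EDGE_MU, sd = EDGE_SD) {
  m1 <- stats::integrate(function(z) tanh(z) * stats::dnorm(z, mu, sd),
                         -Inf, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(z) tanh(z)^2 * stats::dnorm(z, mu, sd),
                         -Inf, Inf, rel.tol = 1e-10)$value
  c(mean = m1, var = m2 - m1^2)
}

#' Noise level giving a target population R-squared for planted edges
#'
#' In the synthetic generator the behaviour change score is a linear
#' combination of the planted signal edges plus Gaussian noise. Signal edges
#' are i.i.d. with a known variance and (by construction) equal coefficient
#' magnitudes `effect_scale`, so the noise standard deviation that yields a
#' given population R-squared (variance explained by the edges, covariates
#' excluded) has a closed form:
#' `noise_sd = sqrt(k * effect_scale^2 * var_edge * (1 - R2) / R2)`.
#'
#' @param n_signal_edges number of planted edges `k`.
#' @param effect_scale common coefficient magnitude.
#' @param target_r2 desired population R-squared in (0, 1).
#' @return the noise standard deviation (behaviour-score units).
#' @export
noise_sd_for_r2 <- function(n_signal_edges, effect_scale, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1, n_signal_edges >= 1)
  v <- tanh_edge_moments()[["var"]]
  sqrt(n_signal_edges * effect_scale^2 * v * (1 - target_r2) / target_r2)
}

#' Generate a synthetic connectome cohort with planted signal edges
#'
#' Draws a cohort of subjects with correlation-valued connectome edges and a
#' continuous behaviour change score (a "delta processing speed"-style
#' score) that is linearly coupled to a known sparse set of signal edges,
#' plus covariate effects and Gaussian noise. The planted truth is recorded
#' so recovery can be checked exactly.
#'
#' Edges are drawn i.i.d. per subject and edge as `tanh(z)`,
#' `z ~ N(0.1, 0.4^2)` — bounded in (-1, 1) with a realistic near-zero
#' centre. Signal edges all carry coefficient `effect_scale` (optionally
#' signed via `effect_signs`), so
#' `behaviour = effect_scale * sum(signs * signal edges) +
#'  covariates %*% covariate_effects + N(0, noise_sd^2)`.
#'
#' Covariates emulate a small neurosurgical cohort: age ~ N(36.6, 9.6^2)
#' years, sex ~ Bernoulli(0.75) (1 = female, mirroring a 9/3 female/male
#' split), education ~ N(13.4, 3.6^2) years.
#'
#' @param n_subjects number of subjects (>= 4; leave-one-out CV with
#'   covariate-controlled selection is undefined below that).
#' @param n_nodes number of parcels; 116 gives the AAL-116 edge space of
#'   6670 edges.
#' @param n_signal_edges number of planted signal edges (may be 0).
#' @param effect_scale common magnitude of the planted edge coefficients.
#' @param noise_sd standard deviation of the additive behavioural noise.
#' @param seed integer seed; identical seeds and parameters reproduce the
#'   cohort bit for bit.
#' @param covariate_effects length-3 numeric (age, sex, education)
#'   coefficients on the behaviour score; defaults to a small realistic set.
#'   Use `c(0, 0, 0)` for an edges-only signal.
#' @param effect_signs optional length-`n_signal_edges` vector of +1/-1
#'   signs; default all +1 (a purely positive network).
#' @return an object of class `"synthetic_cohort"`: a list with
#'   `subject_ids`, `edge_matrix` (n x E, canonical edge order),
#'   `behaviour`, `covariates` (n x 3 matrix: age, sex, education),
#'   `n_nodes`, and `truth` (signal_edges 0-based, edge_effects, noise_sd,
#'   covariate_effects, seed).
#' @examples
#' coh <- generate_cohort(12, n_nodes = 30, n_signal_edges = 5,
#'                        effect_scale = 1, noise_sd = 0.5, seed = 1)
#' dim(coh$edge_matrix)
#' coh$truth$signal_edges
#' @export
generate_cohort <- function(n_subjects, n_nodes = 116, n_signal_edges = 0,
                            effect_scale = 1, noise_sd = 1, seed = 1,
                            covariate_effects = c(age = -0.05, sex = 0.5,
                                                  education = 0.1),
                            effect_signs = NULL) {
  n_subjects <- as.integer(n_subjects)
  n_nodes <- as.integer(n_nodes)
  n_signal_edges <- as.integer(n_signal_edges)
  if (n_subjects < 4) {
    stop("invalid configuration: n_subjects must be >= 4, got ", n_subjects)
  }
  e <- n_edges(n_nodes)
  if (n_signal_edges > e) {
    stop("invalid configuration: n_signal_edges (", n_signal_edges,
         ") exceeds the edge space E = ", e)
  }
  if (!is.finite(effect_scale)) stop("effect_scale must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(length(covariate_effects) == 3)
  if (is.null(effect_signs)) {
    effect_signs <- rep(1, n_signal_edges)
  }
  stopifnot(length(effect_signs) == n_signal_edges,
            all(effect_signs %in% c(-1, 1)))

  with_seed(seed, {
    edge_matrix <- matrix(tanh(stats::rnorm(n_subjects * e, EDGE_MU, EDGE_SD)),
                          nrow = n_subjects, ncol = e)
    age <- stats::rnorm(n_subjects, 36.6, 9.6)
    sex <- stats::rbinom(n_subjects, 1, 0.75)
    education <- stats::rnorm(n_subjects, 13.4, 3.6)
    covariates <- cbind(age = age, sex = sex, education = education)

    signal_edges <- if (n_signal_edges > 0) {
      sort(sample.int(e, n_signal_edges)) - 1L   # 0-based edge indices
    } else integer(0)
    edge_effects <- effect_scale * effect_signs

    signal_part <- if (n_signal_edges > 0) {
      drop(edge_matrix[, signal_edges + 1L, drop = FALSE] %*% edge_effects)
    } else rep(0, n_subjects)
    behaviour <- signal_part +
      drop(covariates %*% as.numeric(covariate_effects)) +
      stats::rnorm(n_subjects, 0, noise_sd)

    structure(list(
      subject_ids = sprintf("S%03d", seq_len(n_subjects)),
      edge_matrix = edge_matrix,
      behaviour = behaviour,
      covariates = covariates,
      n_nodes = n_nodes,
      truth = list(
        signal_edges = signal_edges,
        edge_effects = edge_effects,
        noise_sd = noise_sd,
        covariate_effects = as.numeric(covariate_effects),
        seed = as.integer(seed)
      )
    ), class = "synthetic_cohort")
  })
}

#' @rdname generate_cohort
#' @details `generate_null_cohort()` is `generate_cohort()` with no signal
#'   edges and zero covariate effects: behaviour is pure noise, independent
#'   of every edge. Used for permutation-test calibration experiments.
#' @export
generate_null_cohort <- function(n_subjects, n_nodes = 116, seed = 1,
                                 noise_sd = 1) {
  generate_cohort(n_subjects, n_nodes, n_signal_edges = 0,
                  effect_scale = 0, noise_sd = noise_sd, seed = seed,
                  covariate_effects = c(0, 0, 0))
}

#' Plant a second behaviour score on an existing cohort
#'
#' Real studies measure several change scores (e.g. at 1 and 6 months) on
#' the same connectomes. This draws a fresh signal-edge set and noise for an
#' existing cohort's edge matrix, returning a new behaviour vector and its
#' truth record. Covariate effects are inherited from the call, not the
#' cohort.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @inheritParams generate_cohort
#' @return a list with `behaviour` and `truth` (same shape as in
#'   [generate_cohort()]).
#' @export
plant_behaviour <- function(cohort, n_signal_edges, effect_scale, noise_sd,
                            seed, covariate_effects = c(0, 0, 0),
                            effect_signs = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  e <- ncol(cohort$edge_matrix)
  n <- nrow(cohort$edge_matrix)
  if (n_signal_edges > e) stop("invalid configuration: too many signal edges")
  if (is.null(effect_signs)) effect_signs <- rep(1, n_signal_edges)
  with_seed(seed, {
    signal_edges <- if (n_signal_edges > 0) {
      sort(sample.int(e, n_signal_edges)) - 1L
    } else integer(0)
    edge_effects <- effect_scale * effect_signs
    signal_part <- if (n_signal_edges > 0) {
      drop(cohort$edge_matrix[, signal_edges + 1L, drop = FALSE] %*% edge_effects)
    } else rep(0, n)
    behaviour <- signal_part +
      drop(cohort$covariates %*% as.numeric(covariate_effects)) +
      stats::rnorm(n, 0, noise_sd)
    list(behaviour = behaviour,
         truth = list(signal_edges = signal_edges,
                      edge_effects = edge_effects,
                      noise_sd = noise_sd,
                      covariate_effects = as.numeric(covariate_effects),
                      seed = as.integer(seed)))
  })
}

#' Simulate parcel time series with a target correlation structure
#'
#' Draws multivariate Gaussian volumes whose population correlation matrix
#' equals `target_connectivity`; the sample correlation of the output
#' converges to the target as the number of volumes grows. A typical
#' resting-state run at TR = 3 s yields 155 usable volumes after dummy-scan
#' removal, the default here.
#'
#' If the target is not positive semi-definite it is projected to the
#' nearest correlation-like PSD matrix (negative eigenvalues clipped, then
#' rescaled to unit diagonal) and the result carries attribute
#' `psd_projected = TRUE`.
#'
#' @param n_volumes number of time points (a warning is raised below
#'   `n_nodes + 1`, where the sample correlation is rank deficient).
#' @param n_nodes number of parcels.
#' @param target_connectivity symmetric target correlation matrix; default
#'   identity (independent nodes).
#' @param seed integer seed.
#' @return an `n_volumes x n_nodes` matrix of simulated time series.
#' @export
generate_timeseries <- function(n_volumes = 155, n_nodes = 116,
                                target_connectivity = NULL, seed = 1) {
  n_volumes <- as.integer(n_volumes)
  n_nodes <- as.integer(n_nodes)
  if (is.null(target_connectivity)) target_connectivity <- diag(n_nodes)
  r <- as.matrix(target_connectivity)
  stopifnot(nrow(r) == n_nodes, ncol(r) == n_nodes)
  if (max(abs(r - t(r))) > 1e-8) stop("target connectivity must be symmetric")
  projected <- FALSE
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
    projected <- TRUE
  }
  if (n_volumes < n_nodes + 1) {
    warning("n_volumes < n_nodes + 1: sample correlation will be rank deficient")
  }
  # chol with jitter for semi-definite targets
  ch <- tryCatch(chol(r), error = function(e) chol(r + 1e-10 * diag(n_nodes)))
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_volumes * n_nodes), n_volumes, n_nodes)
    z %*% ch
  })
  if (projected) attr(out, "psd_projected") <- TRUE
  out
}

#' Simulate a rigid-body motion trace with controllable FD spikes
#'
#' Produces a volumes x 6 motion-parameter table (translations in mm,
#' rotations in radians) consisting of smooth bounded low-amplitude drift
#' plus persistent level shifts ("spikes") placed so that framewise
#' displacement exceeds 0.5 mm in approximately `spike_fraction` of volumes.
#' With `spike_fraction = 0` every FD value is strictly below 0.5 mm by
#' construction (drift increments are bounded).
#'
#' @param n_volumes number of volumes.
#' @param spike_fraction fraction of volumes whose FD should exceed 0.5 mm,
#'   in \code{[0, 1]}.
#' @param seed integer seed.
#' @return an `n_volumes x 6` numeric matrix, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
generate_motion_trace <- function(n_volumes = 155, spike_fraction = 0,
                                  seed = 1) {
  n_volumes <- as.integer(n_volumes)
  stopifnot(n_volumes >= 2)
  if (spike_fraction < 0 || spike_fraction > 1) {
    stop("spike_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    # bounded drift: per-volume increments < 0.02 mm / 0.0002 rad per axis,
    # so drift FD <= 3*0.02 + 50*3*0.0002 = 0.09 mm << 0.5 mm
    inc_t <- matrix(stats::runif(3 * (n_volumes - 1), -0.02, 0.02),
                    n_volumes - 1, 3)
    inc_r <- matrix(stats::runif(3 * (n_volumes - 1), -2e-4, 2e-4),
                    n_volumes - 1, 3)
    m <- cbind(rbind(0, apply(inc_t, 2, cumsum)),
               rbind(0, apply(inc_r, 2, cumsum)))
    n_spikes <- round(spike_fraction * (n_volumes - 1))
    if (n_spikes > 0) {
      at <- sort(sample(2:n_volumes, n_spikes))
      for (t in at) {
        axis <- sample.int(3, 1)
        jump <- sample(c(-0.8, 0.8), 1)
        m[t:n_volumes, axis] <- m[t:n_volumes, axis] + jump
      }
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Write / read a synthetic cohort as plain-text files
#'
#' `write_cohort()` writes three files into `dir`: `edges.csv` (subjects x
#' edges, first column `subject_id`, remaining columns named `"i_j"` with
#' 0-based node indices), `pheno.csv` (`subject_id, delta_ps, age, sex,
#' education`), and `truth.json` (the planted ground truth).
#' `read_cohort()` reads them back; the round trip reproduces the cohort.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if missing).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `"synthetic_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- as.data.frame(cohort$edge_matrix)
  names(edges) <- edge_ids(cohort$n_nodes)
  edges <- cbind(subject_id = cohort$subject_ids, edges)
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  pheno <- data.frame(subject_id = cohort$subject_ids,
                      delta_ps = cohort$behaviour,
                      age = cohort$covariates[, "age"],
                      sex = cohort$covariates[, "sex"],
                      education = cohort$covariates[, "education"])
  utils::write.csv(pheno, file.path(dir, "pheno.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  edges <- utils::read.csv(file.path(dir, "edges.csv"), check.names = FALSE)
  pheno <- utils::read.csv(file.path(dir, "pheno.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (length(truth$signal_edges) == 0) truth$signal_edges <- integer(0)
  if (length(truth$edge_effects) == 0) truth$edge_effects <- numeric(0)
  em <- as.matrix(edges[, -1, drop = FALSE])
  dimnames(em) <- NULL
  e <- ncol(em)
  n_nodes <- as.integer(round((1 + sqrt(1 + 8 * e)) / 2))
  structure(list(
    subject_ids = as.character(edges$subject_id),
    edge_matrix = em,
    behaviour = pheno$delta_ps,
    covariates = cbind(age = pheno$age, sex = pheno$sex,
                       education = pheno$education),
    n_nodes = n_nodes,
    truth = truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d nodes (%d edges), %d signal edge(s)\n",
              nrow(x$edge_matrix), x$n_nodes, ncol(x$edge_matrix),
              length(x$truth$signal_edges)))
  invisible(x)
}
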