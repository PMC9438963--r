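#' Behavioural change scores from a three-timepoint table
#'
#' Computes per-contrast change scores from a behaviour table with scores
#' at baseline (T0) and up to two postoperative timepoints (T1, T2):
#' `delta_t1 = ps_t1 - ps_t0` and `delta_t2 = ps_t2 - ps_t0`. Positive
#' values mean improvement relative to baseline. Exclusion is listwise per
#' contrast: a subject missing either score of a contrast is dropped from
#' that contrast only, never imputed.
#'
#' @param behaviour_table data.frame with columns `subject_id`, `ps_t0`,
#'   `ps_t1`, `ps_t2` (scores, `NA` allowed), and covariate columns (e.g.
#'   `age`, `sex`, `education`).
#' @param contrasts which contrasts to compute, subset of
#'   `c("delta_t1", "delta_t2")`.
#' @param min_subjects minimum complete subjects per contrast (default 4;
#'   fewer is an error for that contrast).
#' @return a named list of data.frames, one per contrast, each with
#'   `subject_id`, `delta`, and the covariate columns of the input.
#' @export
compute_deltas <- function(behaviour_table,
                           contrasts = c("delta_t1", "delta_t2"),
                           min_subjects = 4) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  tb <- as.data.frame(behaviour_table)
  stopifnot(all(c("subject_id", "ps_t0") %in% names(tb)))
  covar_cols <- setdiff(names(tb),
                        c("subject_id", "ps_t0", "ps_t1", "ps_t2"))
  out <- list()
  for (ct in contrasts) {
    follow <- if (ct == "delta_t1") "ps_t1" else "ps_t2"
    if (!follow %in% names(tb)) stop("missing column ", follow)
    keep <- !is.na(tb$ps_t0) & !is.na(tb[[follow]])
    if (sum(keep) < min_subjects) {
      stop("contrast ", ct, " has only ", sum(keep),
           " complete subjects (need >= ", min_subjects, ")")
    }
    out[[ct]] <- data.frame(
      subject_id = tb$subject_id[keep],
      delta = tb[[follow]][keep] - tb$ps_t0[keep],
      tb[keep, covar_cols, drop = FALSE],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Study configuration
#'
#' Builds (or reads from a flat YAML file) the configuration object that
#' makes a [run_study()] call fully reproducible: input paths, covariate
#' list, contrasts, threshold grid, permutation settings and seed.
#'
#' @param edges path to the edges CSV (subjects x E, first column
#'   `subject_id`, remaining columns the canonical `"i_j"` edge ids).
#' @param behaviour path to the behaviour CSV (`subject_id, ps_t0, ps_t1,
#'   ps_t2, age, sex, education`).
#' @param out_dir output directory.
#' @param covariates covariate column names used in edge selection.
#' @param contrasts contrasts to analyse.
#' @param grid_start,grid_stop,grid_step selection-threshold grid.
#' @param n_permutations permutation replicates per model.
#' @param seed integer master seed.
#' @param reoptimize rerun the threshold search inside each permutation.
#' @return a list of class `"study_config"`.
#' @export
study_config <- function(edges, behaviour, out_dir,
                         covariates = c("age", "sex", "education"),
                         contrasts = c("delta_t1", "delta_t2"),
                         grid_start = 1e-4, grid_stop = 0.05,
                         grid_step = 1e-4,
                         n_permutations = 5000, seed = 1,
                         reoptimize = FALSE) {
  structure(list(edges = edges, behaviour = behaviour, out_dir = out_dir,
                 covariates = covariates, contrasts = contrasts,
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 reoptimize = isTRUE(reoptimize)),
            class = "study_config")
}

#' @rdname study_config
#' @param path path to a YAML config file with the same keys.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(study_config, cfg)
}

# Atomic write: write to a temporary sibling, then rename, so a failed run
# never leaves a truncated output.
write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

generic_nodes <- function(n) {
  data.frame(node_index = seq_len(n) - 1L,
             aal_name = sprintf("node_%03d", seq_len(n) - 1L),
             abbreviation = sprintf("N%03d", seq_len(n) - 1L),
             hemisphere = NA_character_, stringsAsFactors = FALSE)
}

#' Run the full predictive study
#'
#' The end-to-end analysis on one cohort: per contrast, assemble the
#' edge/behaviour/covariate dataset (listwise per contrast), tune the
#' positive and negative selection thresholds on the grid, fit the
#' leave-one-out CPM at the chosen thresholds, run the permutation test,
#' then apply one Benjamini-Hochberg correction across all contrast x
#' network p-values of the run, extract consensus edges and write every
#' result table to `out_dir`. Reruns with the same config and inputs are
#' byte-identical.
#'
#' Outputs: `summary.csv` (one row per contrast x network), per contrast
#' `predictions_<contrast>.csv`, `consensus_<contrast>_<sign>.csv`,
#' `tuning_<contrast>.json`, plus `provenance.json` (config echo, seed,
#' package version).
#'
#' @param config a [study_config()] or the path to its YAML file.
#' @return (invisibly) a list with the summary data.frame and the per
#'   contrast result objects.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))

  edges_df <- utils::read.csv(config$edges, check.names = FALSE)
  beh_df <- utils::read.csv(config$behaviour)
  if (names(edges_df)[1] != "subject_id") {
    stop("edges file must have subject_id as its first column")
  }
  missing_ids <- setdiff(beh_df$subject_id, edges_df$subject_id)
  extra_ids <- setdiff(edges_df$subject_id, beh_df$subject_id)
  if (length(missing_ids) > 0 || length(extra_ids) > 0) {
    stop("subject-id mismatch between edges and behaviour files; ",
         "missing from edges: [", paste(missing_ids, collapse = ", "),
         "], missing from behaviour: [", paste(extra_ids, collapse = ", "),
         "]")
  }
  edge_mat <- as.matrix(edges_df[, -1, drop = FALSE])
  rownames(edge_mat) <- edges_df$subject_id
  e <- ncol(edge_mat)
  n_nodes <- as.integer(round((1 + sqrt(1 + 8 * e)) / 2))
  nodes <- if (n_nodes == 116) aal116_nodes() else generic_nodes(n_nodes)

  grid <- threshold_grid(config$grid_start, config$grid_stop,
                         config$grid_step)
  deltas <- compute_deltas(beh_df, contrasts = config$contrasts)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary_rows <- list()

  for (ci in seq_along(config$contrasts)) {
    ct <- config$contrasts[ci]
    dd <- deltas[[ct]]
    covs <- as.matrix(dd[, config$covariates, drop = FALSE])
    data <- cohort_dataset(
      edge_mat[as.character(dd$subject_id), , drop = FALSE],
      dd$delta, covariates = covs, subject_ids = dd$subject_id)
    ws <- cpm_workspace(data)

    tune <- optimize_thresholds(data, grid = grid, workspace = ws)
    fit <- loocv_predict(data, tune$chosen_p_pos, tune$chosen_p_neg,
                         workspace = ws, quiet = TRUE)
    perm <- permutation_test(data, tune$chosen_p_pos, tune$chosen_p_neg,
                             n_permutations = config$n_permutations,
                             seed = config$seed + ci,
                             reoptimize = config$reoptimize, grid = grid,
                             workspace = ws)
    cons <- consensus_edges(fit$fold_masks)

    results[[ct]] <- list(tune = tune, fit = fit, perm = perm,
                          consensus = cons, data = data)
    for (sg in c("positive", "negative")) {
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        contrast = ct, network = sg,
        p_threshold = unname(fit$thresholds[sg]),
        rho_true = unname(fit$rho_true[sg]),
        p_permu = perm[[sg]]$p_permu,
        n_subjects = nrow(dd), stringsAsFactors = FALSE)
    }

    write_atomic(function(p) utils::write.csv(data.frame(
      subject_id = data$subject_ids,
      observed = data$behaviour,
      predicted_positive = fit$predicted[, "positive"],
      predicted_negative = fit$predicted[, "negative"]),
      p, row.names = FALSE),
      file.path(config$out_dir, paste0("predictions_", ct, ".csv")))

    for (sg in c("positive", "negative")) {
      lab <- label_edges(cons[[sg]], nodes = nodes,
                         mean_rho = cons$mean_rho)
      write_atomic(function(p) utils::write.csv(lab, p, row.names = FALSE),
                   file.path(config$out_dir,
                             paste0("consensus_", ct, "_", sg, ".csv")))
    }

    write_atomic(function(p) jsonlite::write_json(list(
      contrast = ct,
      chosen_p_pos = tune$chosen_p_pos,
      chosen_p_neg = tune$chosen_p_neg,
      curves = tune$curves), p, auto_unbox = TRUE, digits = NA,
      dataframe = "columns"),
      file.path(config$out_dir, paste0("tuning_", ct, ".json")))
  }

  summary_df <- do.call(rbind, summary_rows)
  summary_df$p_corr <- fdr_correct(summary_df$p_permu)
  write_atomic(function(p) utils::write.csv(summary_df, p, row.names = FALSE),
               file.path(config$out_dir, "summary.csv"))

  # config echo without the output path, so bundles written to different
  # directories from the same inputs and seed stay byte-identical
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL
  write_atomic(function(p) jsonlite::write_json(list(
    package = "cpmpred",
    version = as.character(utils::packageVersion("cpmpred")),
    config = cfg_echo), p, auto_unbox = TRUE, digits = NA),
    file.path(config$out_dir, "provenance.json"))

  invisible(list(summary = summary_df, contrasts = results,
                 config = config))
}
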