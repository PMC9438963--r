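#' Build a functional connectivity matrix from parcel time series
#'
#' Computes the node-by-node Pearson correlation matrix of a parcellated
#' resting-state recording (volumes in rows, parcels in columns), the
#' standard whole-brain functional connectome. The diagonal is set exactly
#' to 1. No Fisher z-transform is applied anywhere in the package: network
#' strengths downstream are sums of raw correlation values.
#'
#' @param timeseries numeric matrix or data.frame, volumes x nodes.
#' @return a symmetric `n_nodes x n_nodes` correlation matrix with unit
#'   diagonal.
#' @examples
#' ts <- matrix(rnorm(155 * 10), 155, 10)
#' fc <- build_connectivity(ts)
#' range(fc[upper.tri(fc)])
#' @export
build_connectivity <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3) stop("need at least 3 volumes, got ", nrow(ts))
  if (anyNA(ts)) stop("time series contains missing values")
  sds <- apply(ts, 2, stats::sd)
  bad <- which(sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance node(s) at 0-based index: ",
         paste(bad - 1L, collapse = ", "))
  }
  fc <- stats::cor(ts)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  dimnames(fc) <- NULL
  fc
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the six rigid-body realignment parameters, with the three
#' rotations converted to arc length on a sphere of radius
#' `rotation_radius_mm` (50 mm by default, the dominant convention). The
#' first volume has FD = 0 by definition. FD is invariant to a constant
#' offset in any parameter.
#'
#' @param motion numeric matrix/data.frame, volumes x 6: three translations
#'   (mm) then three rotations.
#' @param rotation_radius_mm head radius used to convert rotations to mm.
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return numeric vector of per-volume FD in mm.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop("motion table must have 6 columns, got ", ncol(m))
  if (nrow(m) < 2) stop("need at least 2 volumes")
  if (anyNA(m)) stop("motion table contains missing values")
  rot <- m[, 4:6, drop = FALSE]
  if (rotation_units == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(m[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot)) * rotation_radius_mm
  c(0, rowSums(d_trans) + rowSums(d_rot))
}

#' Motion quality control for one subject
#'
#' Applies the three exclusion rules used for resting-state cohorts of this
#' kind: (a) fewer than 20% of volumes may exceed FD 0.5 mm, (b) the maximum
#' absolute translation must not exceed 3 mm and the maximum absolute
#' rotation must not exceed 3 degrees, (c) mean FD must be below 0.2 mm.
#' A subject passes only if all three rules hold.
#'
#' @param motion volumes x 6 motion table (translations mm, then rotations).
#' @param subject_id identifier carried into the report.
#' @param rotation_radius_mm head radius for the FD rotation term.
#' @param rotation_units units of the rotation columns on input.
#' @param fd_spike_mm FD spike threshold (default 0.5 mm).
#' @param max_spike_fraction maximum tolerated fraction of spike volumes
#'   (default 0.20, exclusive).
#' @param max_translation_mm,max_rotation_deg gross-motion limits
#'   (defaults 3 mm and 3 degrees, inclusive).
#' @param max_mean_fd_mm mean-FD limit (default 0.2 mm, exclusive).
#' @return a list of class `"motion_qc"` with fields `subject_id`,
#'   `fd_series`, `mean_fd`, `frac_fd_gt_spike`, `max_translation`,
#'   `max_rotation` (degrees), `passed`, and `reasons` (labels of failed
#'   rules, empty if passed).
#' @export
qc_subject <- function(motion, subject_id = NA_character_,
                       rotation_radius_mm = 50,
                       rotation_units = c("radians", "degrees"),
                       fd_spike_mm = 0.5, max_spike_fraction = 0.20,
                       max_translation_mm = 3, max_rotation_deg = 3,
                       max_mean_fd_mm = 0.2) {
  rotation_units <- match.arg(rotation_units)
  m <- as.matrix(motion)
  fd <- framewise_displacement(m, rotation_radius_mm, rotation_units)
  rot_deg <- m[, 4:6, drop = FALSE]
  if (rotation_units == "radians") rot_deg <- rot_deg * 180 / pi
  frac_spike <- mean(fd > fd_spike_mm)
  max_trans <- max(abs(m[, 1:3]))
  max_rot <- max(abs(rot_deg))
  mean_fd <- mean(fd)

  reasons <- character(0)
  if (!(frac_spike < max_spike_fraction)) {
    reasons <- c(reasons, "fd_spike_fraction")
  }
  if (!(max_trans <= max_translation_mm && max_rot <= max_rotation_deg)) {
    reasons <- c(reasons, "gross_motion")
  }
  if (!(mean_fd < max_mean_fd_mm)) {
    reasons <- c(reasons, "mean_fd")
  }
  structure(list(
    subject_id = subject_id,
    fd_series = fd,
    mean_fd = mean_fd,
    frac_fd_gt_spike = frac_spike,
    max_translation = max_trans,
    max_rotation = max_rot,
    passed = length(reasons) == 0,
    reasons = reasons
  ), class = "motion_qc")
}

#' @export
print.motion_qc <- function(x, ...) {
  cat("Motion QC", if (!is.na(x$subject_id)) paste0("[", x$subject_id, "]"),
      if (x$passed) "PASS" else "FAIL", "\n")
  cat(sprintf("  mean FD %.3f mm | %.1f%% volumes FD > spike | max trans %.2f mm | max rot %.2f deg\n",
              x$mean_fd, 100 * x$frac_fd_gt_spike, x$max_translation,
              x$max_rotation))
  if (!x$passed) cat("  failed rules:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
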