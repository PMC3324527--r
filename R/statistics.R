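# Ensemble statistics: SEM convention, RMSD series, convergence
# diagnostics, secondary-structure propensity aggregation.

#' Trajectory-level mean and standard error
#'
#' The single statistical convention of this package: frames within a
#' trajectory are autocorrelated, so trajectory means are computed first
#' and treated as independent samples. The reported mean is the mean of
#' trajectory means and the SEM is `sd(trajectory means) / sqrt(k)`.
#'
#' @param samples list of numeric vectors, one per trajectory (or a
#'   numeric vector plus a `groups` factor).
#' @param groups optional grouping when `samples` is a plain vector.
#' @return list with `mean`, `sem` (NA with a warning-free flag when only
#'   one trajectory is available), `n_trajectories`.
#' @examples
#' mean_sem(list(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
mean_sem <- function(samples, groups = NULL) {
  if (!is.list(samples)) {
    if (is.null(groups)) stop("supply a list of per-trajectory vectors, ",
                              "or groups for a pooled vector")
    samples <- split(samples, groups)
  }
  tm <- vapply(samples, function(x) mean(as.numeric(x)), numeric(1))
  k <- length(tm)
  list(mean = mean(tm),
       sem = if (k >= 2L) stats::sd(tm) / sqrt(k) else NA_real_,
       n_trajectories = k)
}

#' RMSD time series of a trajectory against a reference
#'
#' Optimal-superposition Calpha RMSD of every frame against the reference
#' conformation (the trajectory's first frame by default), the standard
#' equilibration diagnostic.
#'
#' @param e an [ensemble()].
#' @param trajectory trajectory index.
#' @param reference a [conformation()], or NULL for frame 1.
#' @return numeric vector of per-frame RMSD values, nm.
#' @export
rmsd_series <- function(e, trajectory = 1L, reference = NULL) {
  tr <- e$trajectories[[trajectory]]
  if (is.null(reference)) reference <- get_frame(e, trajectory, 1L)
  ca_ref <- reference$xyz[reference$atoms$atom_name == "CA", , drop = FALSE]
  ca_idx <- which(e$topology$atom_name == "CA")
  vapply(seq_along(tr$times), function(f)
    kabsch_rmsd(tr$xyz[ca_idx, , f], ca_ref) / 10, numeric(1))
}

#' Trajectories with extreme mean RMSD
#'
#' Ranks trajectories by their time-averaged RMSD (each against its own
#' first frame) and returns the `ceiling(k/2)` highest and `floor(k/2)`
#' lowest, for plotting the lower and upper bounds of an ensemble's RMSD
#' spread. For `k = 1` the single highest is returned.
#'
#' @param e an [ensemble()].
#' @param k number of trajectories to select.
#' @return integer vector of trajectory indices (highest first).
#' @export
select_extreme_trajectories <- function(e, k) {
  nt <- n_trajectories(e)
  if (k > nt) stop("k exceeds the number of trajectories")
  avg <- vapply(seq_len(nt), function(ti) mean(rmsd_series(e, ti)),
                numeric(1))
  ord <- order(avg, decreasing = TRUE)
  n_hi <- ceiling(k / 2)
  n_lo <- floor(k / 2)
  c(ord[seq_len(n_hi)],
    if (n_lo > 0) rev(ord)[seq_len(n_lo)] else integer(0))
}

#' Convergence diagnostics for a per-residue statistic
#'
#' Evaluates a per-residue profile over increasing time windows or
#' trajectory counts and reports the maximum absolute change between
#' successive levels. The ensemble is declared converged when the last
#' change falls below the tolerance (monotone in the tolerance by
#' construction).
#'
#' @param e an [ensemble()].
#' @param statistic function of an ensemble returning a
#'   `per_residue_profile` (default [residue_cm_distances()]).
#' @param mode `"time_windows"` (levels are `(start, end]` pairs, ps) or
#'   `"trajectory_counts"` (levels are counts of leading trajectories).
#' @param levels list of window pairs, or integer vector of counts.
#' @param tolerance convergence tolerance in the profile's units
#'   (default 0.5 Angstrom for distance-from-CM profiles).
#' @return object of class `convergence_report`: list with `statistic`,
#'   `mode`, `levels`, `curves`, `max_abs_delta` (between successive
#'   levels), `converged` (NA when fewer than two levels).
#' @export
convergence_check <- function(e, statistic = residue_cm_distances,
                              mode = c("time_windows", "trajectory_counts"),
                              levels, tolerance = 0.5) {
  mode <- match.arg(mode)
  curves <- if (mode == "time_windows") {
    lapply(levels, function(w) statistic(apply_window(e, w)))
  } else {
    lapply(levels, function(k) {
      if (k > n_trajectories(e)) stop("level exceeds trajectory count")
      sub <- e
      sub$trajectories <- e$trajectories[seq_len(k)]
      statistic(sub)
    })
  }
  vals <- lapply(curves, `[[`, "values")
  deltas <- if (length(vals) >= 2L)
    vapply(seq_len(length(vals) - 1L), function(i)
      max(abs(vals[[i + 1L]] - vals[[i]])), numeric(1))
  else numeric(0)
  structure(list(statistic = curves[[1]]$statistic_name, mode = mode,
                 levels = levels, curves = curves, max_abs_delta = deltas,
                 tolerance = tolerance,
                 converged = if (length(deltas))
                   deltas[length(deltas)] < tolerance else NA),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence of", x$statistic, "over", length(x$levels), x$mode,
      "levels\n")
  if (length(x$max_abs_delta))
    cat("  max |delta| between levels:",
        paste(signif(x$max_abs_delta, 3), collapse = ", "), "\n")
  cat("  converged at tolerance", x$tolerance, ":",
      if (is.na(x$converged)) "undefined (single level)" else x$converged,
      "\n")
  invisible(x)
}

#' Write a convergence report as TSV plus a converged flag file
#' @param x a `convergence_report`.
#' @param path output TSV path; a `<path>.converged` flag file is written
#'   alongside.
#' @return invisibly, `path`.
#' @export
write_convergence_report <- function(x, path) {
  mat <- sapply(x$curves, `[[`, "values")
  colnames(mat) <- paste0("level", seq_along(x$curves))
  utils::write.table(data.frame(residue = seq_len(nrow(mat)), mat), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(x$converged), paste0(path, ".converged"))
  invisible(path)
}

#' Secondary-structure propensities from an external label stream
#'
#' Consumes per-frame, per-residue class labels (turn/strand/helix/coil)
#' produced by an external assigner such as STRIDE, and aggregates them
#' into per-residue class propensities (percent) with trajectory-level
#' SEM, plus ensemble averages over residues. Classes are exhaustive and
#' mutually exclusive, so the four percentages sum to 100 at every
#' residue.
#'
#' @param labels character matrix (frames x residues) of single-letter
#'   classes `T`, `E`, `H`, `C`, or a list of such matrices (one per
#'   trajectory).
#' @return list with `per_residue` (one `per_residue_profile` per class),
#'   `ensemble_average` (named percentages) and `classes`.
#' @export
ss_propensity <- function(labels) {
  classes <- c(turn = "T", strand = "E", helix = "H", coil = "C")
  trajs <- if (is.list(labels)) labels else list(labels)
  for (m in trajs) {
    if (!all(m %in% classes))
      stop("unknown secondary-structure label(s): ",
           paste(setdiff(unique(as.vector(m)), classes), collapse = ", "))
    if (ncol(m) != ncol(trajs[[1]]))
      stop("label matrices disagree on residue count")
  }
  n_res <- ncol(trajs[[1]])
  per_res <- lapply(classes, function(cl) {
    per_traj <- vapply(trajs, function(m) colMeans(m == cl) * 100,
                       numeric(n_res))
    per_traj <- matrix(per_traj, nrow = n_res)
    ms <- .rowwise_mean_sem(per_traj)
    structure(list(statistic_name = paste0("ss_", cl), values = ms$mean,
                   sem = ms$sem, units = "percent"),
              class = "per_residue_profile")
  })
  names(per_res) <- names(classes)
  list(per_residue = per_res,
       ensemble_average = vapply(per_res, function(p) mean(p$values),
                                 numeric(1)),
       classes = classes)
}

#' Read a secondary-structure label stream
#'
#' Format: one line per frame, one single-letter class per residue
#' (`T`/`E`/`H`/`C`), optionally whitespace-separated.
#'
#' @param path text file path.
#' @return character matrix, frames x residues.
#' @export
read_ss_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    l <- gsub("[[:space:]]", "", l)
    strsplit(l, "")[[1]]
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("label lines have inconsistent residue counts")
  do.call(rbind, rows)
}
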