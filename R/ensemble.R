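#' Construct an ensemble of trajectories
#'
#' An ensemble is an ordered set of trajectories sharing one topology.
#' Each trajectory stores its frame times (ps) and a 3-D coordinate array
#' `n_atoms x 3 x n_frames`. The analysis window is half-open at the start,
#' `(t_start, t_end]`, so a 50 ns trajectory recorded every 50 ps contributes
#' exactly 600 frames to the standard 20-50 ns window.
#'
#' @param topology atom table (as in [conformation()]).
#' @param trajectories list; each element a list with `times` (ps, strictly
#'   increasing) and `xyz` (array `n_atoms x 3 x n_frames`).
#' @param interval recording interval, ps.
#' @param window length-2 numeric `(t_start, t_end]` in ps, or NULL for all.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(topology, trajectories, interval, window = NULL) {
  for (tr in trajectories) {
    if (is.null(dim(tr$xyz)) || length(dim(tr$xyz)) != 3L)
      stop("trajectory xyz must be an n_atoms x 3 x n_frames array")
    if (dim(tr$xyz)[1] != nrow(topology))
      stop("trajectory does not match topology atom count")
    if (length(tr$times) != dim(tr$xyz)[3])
      stop("times length must equal frame count")
    if (length(tr$times) > 1L && any(diff(tr$times) <= 0))
      stop("frame times must be strictly increasing within a trajectory")
  }
  obj <- structure(list(topology = topology, trajectories = trajectories,
                        interval = interval, window = window),
                   class = "ensemble")
  if (!is.null(window)) obj <- apply_window(obj, window)
  obj
}

#' Restrict an ensemble to an analysis window
#'
#' Keeps frames with `t_start < t <= t_end`. Idempotent: applying the same
#' window twice equals applying it once.
#'
#' @param e an `ensemble`.
#' @param window length-2 numeric, ps.
#' @return windowed `ensemble`; its `empty` flag is TRUE when no frames remain.
#' @export
apply_window <- function(e, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  e$trajectories <- lapply(e$trajectories, function(tr) {
    keep <- tr$times > window[1] & tr$times <= window[2]
    list(times = tr$times[keep],
         xyz = tr$xyz[, , keep, drop = FALSE])
  })
  e$window <- window
  e$empty <- n_frames(e) == 0L
  e
}

#' Total number of frames in an ensemble
#' @param e an `ensemble`.
#' @return integer count over all trajectories.
#' @export
n_frames <- function(e) {
  sum(vapply(e$trajectories, function(tr) length(tr$times), integer(1)))
}

#' Number of trajectories
#' @param e an `ensemble`.
#' @return integer.
#' @export
n_trajectories <- function(e) length(e$trajectories)

#' Extract one frame as a conformation
#' @param e an `ensemble`.
#' @param trajectory trajectory index.
#' @param frame frame index within the trajectory.
#' @return a `conformation`.
#' @export
get_frame <- function(e, trajectory, frame) {
  tr <- e$trajectories[[trajectory]]
  conformation(e$topology, tr$xyz[, , frame],
               frame_time = tr$times[frame], validate = FALSE)
}

#' Apply a function to every frame
#' @param e an `ensemble`.
#' @param f function of a `conformation`.
#' @param simplify passed to [sapply()]-style simplification (default TRUE).
#' @return list (or simplified vector) per trajectory of per-frame results.
#' @export
map_frames <- function(e, f, simplify = TRUE) {
  lapply(seq_along(e$trajectories), function(i) {
    tr <- e$trajectories[[i]]
    nf <- length(tr$times)
    out <- lapply(seq_len(nf), function(j) f(get_frame(e, i, j)))
    if (simplify) simplify2array(out) else out
  })
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_trajectories(x), "trajectories,", n_frames(x),
      "frames,", nrow(x$topology), "atoms")
  if (!is.null(x$window))
    cat(sprintf(", window (%g, %g] ps", x$window[1], x$window[2]))
  cat("\n")
  invisible(x)
}

#' Frames recorded in a half-open window
#'
#' Counts recording events at `interval, 2*interval, ...` falling in
#' `(t_start, t_end]`; this is the arithmetic behind per-trajectory
#' conformation counts (e.g. 600 frames for a (20, 50] ns window at 50 ps).
#'
#' @param t_start,t_end window bounds, ps.
#' @param interval recording interval, ps.
#' @return integer frame count.
#' @export
count_window_frames <- function(t_start, t_end, interval) {
  as.integer(floor(t_end / interval) - floor(t_start / interval))
}

#' Trajectory bookkeeping for an ensemble study
#'
#' Given per-condition trajectory counts, computes the totals a study
#' reports: total trajectories, total simulation time, and conformations
#' entering structural analysis per condition.
#'
#' @param n_trajectories integer vector (one entry per condition cell).
#' @param trajectory_ns length of each trajectory, ns (default 50).
#' @param interval_ps recording interval, ps (default 50).
#' @param window_ns analysis window `(start, end]`, ns (default `c(20, 50)`).
#' @return list with `total_trajectories`, `total_time_us`,
#'   `frames_per_trajectory`, and `conformations` (per condition cell).
#' @examples
#' bk <- trajectory_bookkeeping(c(44, 41, 49, 42, 45, 39, 42, 41))
#' bk$total_trajectories  # 343
#' bk$total_time_us       # 17.15
#' @export
trajectory_bookkeeping <- function(n_trajectories, trajectory_ns = 50,
                                   interval_ps = 50,
                                   window_ns = c(20, 50)) {
  fpt <- count_window_frames(window_ns[1] * 1000, window_ns[2] * 1000,
                             interval_ps)
  list(total_trajectories = sum(n_trajectories),
       total_time_us = sum(n_trajectories) * trajectory_ns / 1000,
       frames_per_trajectory = fpt,
       conformations = as.integer(n_trajectories) * fpt)
}

#' Bundled reference trajectory counts per study condition
#'
#' Trajectory counts for the eight condition cells (alloform x assembly
#' state x water model) of the reference monomer/dimer ensemble study,
#' shipped as a plain-text TSV. Used as input to
#' [trajectory_bookkeeping()].
#'
#' @return data frame with columns `alloform`, `assembly`, `water`,
#'   `n_trajectories`.
#' @export
reference_trajectory_counts <- function() {
  utils::read.delim(system.file("extdata", "trajectory_counts.tsv",
                                package = "abensemble", mustWork = TRUE))
}

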