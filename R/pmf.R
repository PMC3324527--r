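# 2D potential-of-mean-force landscapes from reaction-coordinate samples.

#' Two-dimensional potential of mean force
#'
#' Bins per-frame values of two reaction coordinates into an
#' `n_bins x n_bins` normalized histogram and converts bin occupancies to
#' free energies via Boltzmann inversion, `pmf_i = -ln(N_i / N)`, in units
#' of kT. The reported surface is shifted so the global minimum is 0 kT
#' (relative free energy). Empty bins are left as `NA` ("not sampled"),
#' never as a large finite value, so they cannot masquerade as barriers.
#'
#' @param x,y numeric vectors of per-frame reaction-coordinate values.
#' @param n_bins bins per axis (default 40). Bins span the data range of
#'   each coordinate; the last bin is right-closed.
#' @return object of class `pmf_grid`: list with `x_name`, `y_name`,
#'   `x_edges`, `y_edges`, `counts`, `pmf` (min-shifted, NA for empty
#'   bins), `pmf_raw` (unshifted -ln(N_i/N)), and `frame_index` (per-bin
#'   list of contributing frame indices).
#' @export
compute_pmf <- function(x, y, n_bins = 40L,
                        x_name = deparse(substitute(x)),
                        y_name = deparse(substitute(y))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 1L) stop("zero frames: cannot compute a PMF")
  xe <- .pmf_edges(x, n_bins)
  ye <- .pmf_edges(y, n_bins)
  bx <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), n_bins)
  by <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  flat <- (by - 1L) * n_bins + bx
  tab <- tabulate(flat, nbins = n_bins * n_bins)
  counts[] <- tab
  frame_index <- split(seq_len(n), factor(flat, levels = seq_len(n_bins^2)))
  pmf_raw <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0L
  pmf_raw[occ] <- -log(counts[occ] / n)
  pmf <- pmf_raw - min(pmf_raw, na.rm = TRUE)
  structure(list(x_name = x_name, y_name = y_name,
                 x_edges = xe, y_edges = ye, counts = counts,
                 pmf = pmf, pmf_raw = pmf_raw, n_total = n,
                 frame_index = frame_index),
            class = "pmf_grid")
}

#' @keywords internal
.pmf_edges <- function(v, n_bins) {
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1L)
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("PMF grid:", length(x$x_edges) - 1L, "x", length(x$y_edges) - 1L,
      "bins,", x$n_total, "frames,", sum(x$counts > 0), "occupied bins\n")
  invisible(x)
}

#' Frames populating the lowest free-energy basin
#'
#' Returns the frames in every bin whose PMF lies within `depth` kT of the
#' global minimum. With the default depth the selection typically contains
#' on the order of one to two hundred conformations for ensembles of a few
#' tens of thousands of frames, suitable for representative-structure
#' clustering.
#'
#' @param g a `pmf_grid`.
#' @param depth energy window above the minimum, kT (default 0.1).
#' @return integer vector of frame indices.
#' @export
lowest_basin_frames <- function(g, depth = 0.1) {
  if (!any(is.finite(g$pmf))) stop("PMF grid has no finite bins")
  sel <- which(g$pmf <= depth)
  sort(unlist(g$frame_index[sel], use.names = FALSE))
}

#' Write a PMF grid as TSV (x_low, x_high, y_low, y_high, count, pmf)
#' @param g a `pmf_grid`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pmf <- function(g, path) {
  nb_x <- length(g$x_edges) - 1L
  nb_y <- length(g$y_edges) - 1L
  ix <- rep(seq_len(nb_x), times = nb_y)
  iy <- rep(seq_len(nb_y), each = nb_x)
  utils::write.table(
    data.frame(x_low = g$x_edges[ix], x_high = g$x_edges[ix + 1L],
               y_low = g$y_edges[iy], y_high = g$y_edges[iy + 1L],
               count = as.vector(g$counts),
               pmf = as.vector(g$pmf)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
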