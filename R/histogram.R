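#' Density-normalized histogram with trajectory-level SEM
#'
#' Builds a probability-density histogram (the densities integrate to 1)
#' of a reaction-coordinate sample, with per-bin SEM computed across
#' trajectories: each trajectory's own density histogram is treated as an
#' independent sample of the distribution.
#'
#' @param values numeric vector of pooled samples, or a list of numeric
#'   vectors (one per trajectory; required for SEM).
#' @param n_bins number of equal-width bins spanning the pooled data range.
#' @return object of class `histogram1d`: list with `bin_edges`, `density`,
#'   `sem`, `counts`.
#' @export
distribution <- function(values, n_bins = 30L) {
  groups <- if (is.list(values)) values else list(values)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 2L) stop("need at least 2 samples")
  rng <- range(pooled)
  if (diff(rng) == 0) { rng <- rng + c(-0.5, 0.5); n_bins <- 1L }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  width <- diff(edges)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  counts <- tabulate(bin_of(pooled), nbins = n_bins)
  dens <- counts / sum(counts) / width
  k <- length(groups)
  sem <- if (k >= 2L) {
    per <- vapply(groups, function(g) {
      cg <- tabulate(bin_of(g), nbins = n_bins)
      cg / sum(cg) / width
    }, numeric(n_bins))
    per <- matrix(per, nrow = n_bins)
    apply(per, 1L, stats::sd) / sqrt(k)
  } else rep(NA_real_, n_bins)
  structure(list(bin_edges = edges, density = dens, sem = sem,
                 counts = counts),
            class = "histogram1d")
}

#' @export
print.histogram1d <- function(x, ...) {
  cat("histogram1d:", length(x$density), "bins, integral",
      format(sum(x$density * diff(x$bin_edges))), "\n")
  invisible(x)
}
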