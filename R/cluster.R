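# Optimal-superposition RMSD (Kabsch) and GROMOS-style clustering.

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Kabsch algorithm: both sets are centered, the optimal rotation is found
#' from the SVD of the covariance matrix (with a determinant correction so
#' the result is a proper rotation), and the RMSD of the superposed sets
#' is returned.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom), matched atom order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("coordinate sets must match in size")
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(sum((ac %*% rot - bc)^2) / nrow(a))
}

#' Pairwise RMSD between two conformations
#'
#' Minimal RMSD over rigid-body superpositions of the selected atoms
#' (Calpha atoms by default), reported in nm.
#'
#' @param a,b [conformation()] objects with matched topologies.
#' @param selection optional logical vector or function of the atom table;
#'   defaults to Calpha atoms.
#' @return RMSD in nm.
#' @export
pairwise_rmsd <- function(a, b, selection = NULL) {
  sel_a <- .rmsd_selection(a, selection)
  sel_b <- .rmsd_selection(b, selection)
  if (sum(sel_a) != sum(sel_b)) stop("atom selections do not match")
  kabsch_rmsd(a$xyz[sel_a, , drop = FALSE],
              b$xyz[sel_b, , drop = FALSE]) / 10
}

#' @keywords internal
.rmsd_selection <- function(c, selection) {
  if (is.null(selection)) c$atoms$atom_name == "CA"
  else .resolve_selection(c, selection)
}

#' GROMOS-style RMSD clustering
#'
#' Iterative neighbor-count clustering: the frame with the most neighbors
#' within the RMSD cutoff becomes a cluster centroid; it and its neighbors
#' are removed; the procedure repeats on the remainder. Ties (equal
#' neighbor counts, and equal final cluster sizes) are broken by the
#' lowest frame index, making the output deterministic and invariant
#' under input permutation.
#'
#' @param frames list of [conformation()] objects.
#' @param cutoff RMSD cutoff, nm (default 0.3).
#' @param selection atom selection for the RMSD (default Calpha).
#' @return object of class `cluster_result`: list with `clusters` (list of
#'   integer frame-index vectors, sizes non-increasing), `centroid`
#'   (one frame index per cluster), `cutoff`, `rmsd` (the pairwise matrix,
#'   nm).
#' @export
gromos_cluster <- function(frames, cutoff = 0.3, selection = NULL) {
  n <- length(frames)
  if (n < 1L) stop("need at least one frame")
  rm <- matrix(0, n, n)
  if (n > 1L) {
    coords <- lapply(frames, function(f) {
      sel <- .rmsd_selection(f, selection)
      f$xyz[sel, , drop = FALSE]
    })
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      rm[i, j] <- rm[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]]) / 10
    }
  }
  remaining <- seq_len(n)
  clusters <- list(); centroids <- integer(0)
  while (length(remaining)) {
    nb <- colSums(rm[remaining, remaining, drop = FALSE] <= cutoff)
    # lowest frame index wins ties: remaining is kept sorted ascending
    ctr <- remaining[which.max(nb)]
    members <- remaining[rm[ctr, remaining] <= cutoff]
    clusters[[length(clusters) + 1L]] <- sort(members)
    centroids <- c(centroids, ctr)
    remaining <- setdiff(remaining, members)
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, integer(1)))
  structure(list(clusters = clusters[ord], centroid = centroids[ord],
                 cutoff = cutoff, rmsd = rm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("GROMOS clustering:", length(x$clusters), "clusters, sizes",
      paste(lengths(x$clusters), collapse = ", "),
      "(cutoff", x$cutoff, "nm)\n")
  invisible(x)
}

#' Representative conformation of an ensemble subset
#'
#' Clusters the given frames with [gromos_cluster()] and returns the
#' centroid of the largest cluster, the standard choice of a single
#' representative structure of a free-energy basin.
#'
#' @param frames list of [conformation()] objects.
#' @param cutoff RMSD cutoff, nm.
#' @param selection atom selection (default Calpha).
#' @return list with `frame` (index into `frames`), `conformation`, and
#'   the full `cluster_result`.
#' @export
representative_conformation <- function(frames, cutoff = 0.3,
                                        selection = NULL) {
  cl <- gromos_cluster(frames, cutoff = cutoff, selection = selection)
  idx <- cl$centroid[1]
  list(frame = idx, conformation = frames[[idx]], clustering = cl)
}

#' Write cluster membership as TSV (frame, cluster, is_centroid)
#' @param x a `cluster_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clusters <- function(x, path) {
  rows <- do.call(rbind, lapply(seq_along(x$clusters), function(k)
    data.frame(frame = x$clusters[[k]], cluster = k,
               is_centroid = x$clusters[[k]] == x$centroid[k])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
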