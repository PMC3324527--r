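# Center-of-mass geometry, contact numbers and contact maps.

#' Mass-weighted center of mass
#'
#' @param c a [conformation()].
#' @param selection optional logical vector (or function of the atom table
#'   returning one) choosing atoms; defaults to all atoms. Waters and ions
#'   never enter the conformation container, so they are always excluded.
#' @return length-3 numeric, Angstrom.
#' @export
center_of_mass <- function(c, selection = NULL) {
  sel <- .resolve_selection(c, selection)
  if (!any(sel)) stop("empty atom selection for center of mass")
  m <- c$atoms$mass[sel]
  colSums(c$xyz[sel, , drop = FALSE] * m) / sum(m)
}

#' @keywords internal
.resolve_selection <- function(c, selection) {
  if (is.null(selection)) rep(TRUE, nrow(c$atoms))
  else if (is.function(selection)) selection(c$atoms)
  else selection
}

#' Radius of gyration
#'
#' `sqrt(sum m_i |r_i - r_cm|^2 / sum m_i)`, mass-weighted, Angstrom.
#'
#' @param c a [conformation()].
#' @param selection as in [center_of_mass()].
#' @return numeric, Angstrom.
#' @export
radius_of_gyration <- function(c, selection = NULL) {
  sel <- .resolve_selection(c, selection)
  if (!any(sel)) stop("empty atom selection")
  m <- c$atoms$mass[sel]
  r <- c$xyz[sel, , drop = FALSE]
  cm <- colSums(r * m) / sum(m)
  d2 <- rowSums(sweep(r, 2L, cm)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Distance of each residue's Calpha from the assembly center of mass
#'
#' For every frame the assembly CM is computed, then the distance of each
#' residue's Calpha from it. Residue-wise means and trajectory-level SEMs
#' are returned; in dimers both peptides contribute samples for a residue.
#'
#' @param e an [ensemble()].
#' @return a `per_residue_profile`: list with `statistic_name`, `values`
#'   (per-residue mean, Angstrom), `sem` and `units`.
#' @export
residue_cm_distances <- function(e) {
  if (n_frames(e) == 0L) stop("empty ensemble")
  top <- e$topology
  ca <- which(top$atom_name == "CA")
  res <- top$residue_index[ca]
  n_res <- max(res)
  traj_means <- sapply(seq_along(e$trajectories), function(ti) {
    tr <- e$trajectories[[ti]]
    acc <- matrix(0, nrow = length(ca), ncol = length(tr$times))
    for (f in seq_along(tr$times)) {
      xyz <- tr$xyz[, , f]
      cm <- colSums(xyz * top$mass) / sum(top$mass)
      acc[, f] <- sqrt(rowSums(sweep(xyz[ca, , drop = FALSE], 2L, cm)^2))
    }
    # pool the two peptides' samples per residue, then average over frames
    as.vector(tapply(rowMeans(acc), factor(res, levels = seq_len(n_res)), mean))
  })
  traj_means <- matrix(traj_means, nrow = n_res)
  ms <- .rowwise_mean_sem(traj_means)
  structure(list(statistic_name = "distance_from_cm",
                 values = ms$mean, sem = ms$sem, units = "Angstrom"),
            class = "per_residue_profile")
}

#' @keywords internal
.rowwise_mean_sem <- function(m) {
  k <- ncol(m)
  list(mean = rowMeans(m),
       sem = if (k >= 2L) apply(m, 1L, stats::sd) / sqrt(k) else rep(NA_real_, nrow(m)))
}

#' @export
print.per_residue_profile <- function(x, ...) {
  cat("per-residue profile:", x$statistic_name, "(", x$units, "),",
      length(x$values), "residues\n")
  invisible(x)
}

#' N-terminal Calpha to center-of-mass distance (effective radius)
#'
#' Distance from each peptide's residue-1 Calpha to the CM of the whole
#' assembly. Because the N-terminus is the most solvent-exposed part of a
#' quasi-spherical amyloid-beta assembly, this serves as an effective
#' radius reaction coordinate.
#'
#' @param c a [conformation()].
#' @return numeric vector, one value per peptide, Angstrom.
#' @export
nt_cm_distance <- function(c) {
  cm <- center_of_mass(c)
  peps <- sort(unique(c$atoms$peptide_id))
  vapply(peps, function(p) {
    sel <- c$atoms$peptide_id == p & c$atoms$residue_index == 1L &
      c$atoms$atom_name == "CA"
    if (!any(sel)) stop("peptide ", p, ": residue 1 has no CA atom")
    sqrt(sum((c$xyz[which(sel)[1], ] - cm)^2))
  }, numeric(1))
}

#' Interpeptide contact number of a dimer
#'
#' Counts residue pairs (i in peptide 1, j in peptide 2) whose Calpha atoms
#' are strictly closer than the cutoff. A proxy for the interface area that
#' stabilizes a dimer.
#'
#' @param c a [conformation()]; must be a dimer.
#' @param cutoff Calpha-Calpha cutoff, Angstrom (default 7.5).
#' @return integer count.
#' @export
contact_number <- function(c, cutoff = 7.5) {
  if (!is_dimer(c)) stop("contact_number requires a dimer conformation")
  a <- calpha_coords(c, 1L)
  b <- calpha_coords(c, 2L)
  d2 <- .cross_dist2(a, b)
  sum(d2 < cutoff^2)
}

#' Squared distances between two coordinate sets
#' @keywords internal
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  pmax(d2, 0)   # guard against tiny negative values from cancellation
}

#' Intra- or intermolecular contact map of an ensemble
#'
#' Contact indicator (Calpha pair strictly below the cutoff) averaged over
#' frames. In dimers the intramolecular map averages over both peptides;
#' the intermolecular map is symmetrized over peptide order so the result
#' does not depend on chain labeling in the input. SEM is computed across
#' trajectories.
#'
#' @param e an [ensemble()].
#' @param cutoff Angstrom (default 7.5).
#' @param kind `"intra"` or `"inter"`.
#' @return a `contact_map`: list with `kind`, `matrix` (mean contact
#'   probability), `sem`, `cutoff`, `n_conformations`.
#' @export
contact_map <- function(e, cutoff = 7.5, kind = c("intra", "inter")) {
  kind <- match.arg(kind)
  if (n_frames(e) == 0L) stop("empty ensemble")
  peps <- sort(unique(e$topology$peptide_id))
  if (kind == "inter" && length(peps) != 2L)
    stop("intermolecular contact map requires a dimer ensemble")
  n_res <- max(e$topology$residue_index)
  c2 <- cutoff^2
  per_traj <- lapply(e$trajectories, function(tr) {
    acc <- matrix(0, n_res, n_res)
    nf <- length(tr$times)
    for (f in seq_len(nf)) {
      frame <- conformation(e$topology, tr$xyz[, , f], validate = FALSE)
      if (kind == "intra") {
        for (p in peps) {
          ca <- calpha_coords(frame, p)
          idx <- as.integer(rownames(ca))
          d2 <- .cross_dist2(ca, ca)
          acc[idx, idx] <- acc[idx, idx] + (d2 < c2) / length(peps)
        }
      } else {
        ca1 <- calpha_coords(frame, 1L); ca2 <- calpha_coords(frame, 2L)
        i1 <- as.integer(rownames(ca1)); i2 <- as.integer(rownames(ca2))
        d2 <- .cross_dist2(ca1, ca2)
        ind <- matrix(0, n_res, n_res)
        ind[i1, i2] <- (d2 < c2)
        acc <- acc + (ind + t(ind)) / 2   # symmetrize over peptide order
      }
    }
    acc / nf
  })
  k <- length(per_traj)
  mean_map <- Reduce(`+`, per_traj) / k
  sem_map <- if (k >= 2L) {
    s2 <- Reduce(`+`, lapply(per_traj, function(m) (m - mean_map)^2)) / (k - 1)
    sqrt(s2 / k)
  } else matrix(NA_real_, n_res, n_res)
  structure(list(kind = kind, matrix = mean_map, sem = sem_map,
                 cutoff = cutoff, n_conformations = n_frames(e)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(x$kind, "contact map:", nrow(x$matrix), "x", ncol(x$matrix),
      "residues, cutoff", x$cutoff, "A,", x$n_conformations, "conformations\n")
  invisible(x)
}

#' Write a contact map (and its SEM) as TSV
#' @param m a `contact_map`.
#' @param path output TSV path; SEM written alongside as `<path>.sem.tsv`.
#' @return invisibly, `path`.
#' @export
write_contact_map <- function(m, path) {
  utils::write.table(m$matrix, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  utils::write.table(m$sem, paste0(path, ".sem.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a per-residue profile as TSV (residue, mean, sem)
#' @param p a `per_residue_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profile <- function(p, path) {
  utils::write.table(
    data.frame(residue = seq_along(p$values), mean = p$values, sem = p$sem),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
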