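# Four-bead coarse-grained -> united-atom reconstruction: side-chain
# template grafting followed by Monte Carlo clash relief under a hard
# bead-RMSD constraint.

#' Side-chain template library
#'
#' One template per residue type: the united-atom (heavy atoms only)
#' side-chain composition from the package's residue table, with
#' idealized schematic coordinates (atoms laid out along a compact helix
#' with ~1.5 Angstrom spacing, centered on their centroid). Template
#' geometry is schematic by design: the reconstruction contract is exact
#' heavy-atom composition, clash relief, and the bead-RMSD bound, not
#' rotamer-accurate side chains.
#'
#' @return named list of templates; each has `atoms` (name, element) and
#'   `coords` (centroid-centered local coordinates).
#' @export
sidechain_templates <- function() {
  out <- lapply(.aa1, function(code) {
    nm <- sidechain_atom_names(code)
    m <- length(nm)
    if (m == 0L)
      return(list(atoms = data.frame(atom_name = character(0),
                                     element = character(0)),
                  coords = matrix(numeric(0), 0, 3)))
    t <- (seq_len(m) - 1) * 0.9
    coords <- cbind(0.8 * cos(2 * t), 0.8 * sin(2 * t), 1.1 * t)
    coords <- sweep(coords, 2L, colMeans(coords))
    list(atoms = data.frame(atom_name = nm,
                            element = element_from_atom_name(nm),
                            stringsAsFactors = FALSE),
         coords = coords)
  })
  names(out) <- .aa1
  out
}

#' Rotation taking the +z axis onto a given direction
#' @keywords internal
.rotation_z_to <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-10) return(diag(3))
  v <- v / nrm
  z <- c(0, 0, 1)
  axis <- c(z[2] * v[3] - z[3] * v[2],
            z[3] * v[1] - z[1] * v[3],
            z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(axis^2)); cth <- sum(z * v)
  if (s < 1e-10) return(if (cth > 0) diag(3) else diag(c(1, -1, -1)))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

#' Graft side-chain templates onto a four-bead conformation
#'
#' Backbone heavy atoms N, CA, C are taken from the beads directly; a
#' carbonyl O is added at idealized geometry off the C bead. Each residue's
#' side-chain template is rigidly placed with its centroid on the
#' side-chain bead, oriented deterministically along the CA-to-bead
#' direction. Glycine contributes backbone only.
#'
#' @param cg four-bead [conformation()] (bead names N, CA, C, CB).
#' @param templates template library (default [sidechain_templates()]).
#' @return united-atom [conformation()].
#' @export
graft_side_chains <- function(cg, templates = sidechain_templates()) {
  a <- cg$atoms
  rows <- list(); coords <- list()
  for (pep in sort(unique(a$peptide_id))) {
    res_idx <- sort(unique(a$residue_index[a$peptide_id == pep]))
    for (i in res_idx) {
      sel <- a$peptide_id == pep & a$residue_index == i
      code <- a$residue_code[which(sel)[1]]
      bead <- function(nm) {
        k <- which(sel & a$atom_name == nm)
        if (!length(k)) stop("residue ", code, i, " (peptide ", pep,
                             "): missing bead ", nm)
        cg$xyz[k[1], ]
      }
      nN <- bead("N"); nCA <- bead("CA"); nC <- bead("C")
      rows[[length(rows) + 1L]] <- .atom_block(pep, i, code, "N", "N")
      coords[[length(coords) + 1L]] <- nN
      rows[[length(rows) + 1L]] <- .atom_block(pep, i, code, "CA", "C")
      coords[[length(coords) + 1L]] <- nCA
      rows[[length(rows) + 1L]] <- .atom_block(pep, i, code, "C", "C")
      coords[[length(coords) + 1L]] <- nC
      # carbonyl O at 1.23 A off the C bead, perpendicular-ish to CA->C
      u <- nC - nCA; un <- sqrt(sum(u^2))
      u <- if (un < 1e-8) c(0, 0, 1) else u / un
      perp <- c(-u[2], u[1], 0)
      pn <- sqrt(sum(perp^2))
      perp <- if (pn < 1e-8) c(1, 0, 0) else perp / pn
      rows[[length(rows) + 1L]] <- .atom_block(pep, i, code, "O", "O")
      coords[[length(coords) + 1L]] <- nC + 1.23 * perp
      if (code != "G") {
        k <- which(sel & a$atom_name == "CB")
        if (!length(k)) stop("residue ", code, i, " (peptide ", pep,
                             "): missing side-chain bead CB")
        bpos <- cg$xyz[k[1], ]
        tpl <- templates[[code]]
        rot <- .rotation_z_to(bpos - nCA)
        placed <- sweep(tpl$coords %*% t(rot), 2L, bpos, "+")
        for (j in seq_len(nrow(tpl$atoms))) {
          rows[[length(rows) + 1L]] <- .atom_block(pep, i, code,
                                                   tpl$atoms$atom_name[j],
                                                   tpl$atoms$element[j])
          coords[[length(coords) + 1L]] <- placed[j, ]
        }
      }
    }
  }
  conformation(do.call(rbind, rows), do.call(rbind, coords))
}

#' Map a united-atom conformation back to four-bead positions
#'
#' N, CA, C beads are the backbone atom positions; the side-chain bead is
#' the centroid of the residue's side-chain heavy atoms (absent for Gly).
#'
#' @param c united-atom [conformation()].
#' @return matrix of bead coordinates in the same order as
#'   [gen_cg_conformer()] emits beads (N, CA, C, CB per residue).
#' @export
map_to_beads <- function(c) {
  a <- c$atoms
  out <- list()
  for (pep in sort(unique(a$peptide_id))) {
    for (i in sort(unique(a$residue_index[a$peptide_id == pep]))) {
      sel <- a$peptide_id == pep & a$residue_index == i
      for (nm in c("N", "CA", "C"))
        out[[length(out) + 1L]] <- c$xyz[which(sel & a$atom_name == nm)[1], ]
      sc <- sel & !(a$atom_name %in% c("N", "CA", "C", "O", "OXT"))
      if (any(sc))
        out[[length(out) + 1L]] <- colMeans(c$xyz[sc, , drop = FALSE])
    }
  }
  do.call(rbind, out)
}

#' Bead coordinates of a four-bead conformation (N, CA, C, CB order)
#' @keywords internal
.cg_bead_coords <- function(cg) {
  a <- cg$atoms
  out <- list()
  for (pep in sort(unique(a$peptide_id))) {
    for (i in sort(unique(a$residue_index[a$peptide_id == pep]))) {
      sel <- a$peptide_id == pep & a$residue_index == i
      for (nm in c("N", "CA", "C", "CB")) {
        k <- which(sel & a$atom_name == nm)
        if (length(k)) out[[length(out) + 1L]] <- cg$xyz[k[1], ]
      }
    }
  }
  do.call(rbind, out)
}

#' RMSD between mapped beads and source beads (no re-superposition)
#' @param c united-atom [conformation()].
#' @param cg source four-bead [conformation()].
#' @return RMSD in Angstrom over matched bead positions.
#' @export
bead_rmsd <- function(c, cg) {
  m <- map_to_beads(c)
  s <- .cg_bead_coords(cg)
  if (nrow(m) != nrow(s)) stop("bead sets do not match")
  sqrt(mean(rowSums((m - s)^2)))
}

#' Soft-sphere clash energy
#'
#' `E = sum over pairs max(0, sigma_ij - d_ij)^2` with
#' `sigma_ij = 0.9 * (vdw_i + vdw_j)`, over atom pairs of different
#' residues, excluding backbone-backbone pairs of adjacent residues
#' (which are covalently constrained). E >= 0, and E = 0 iff no pair is
#' closer than its sigma.
#'
#' @param c a [conformation()].
#' @return numeric energy (Angstrom^2 units).
#' @export
clash_energy <- function(c) {
  pr <- .clash_pairs(c)
  if (!nrow(pr)) return(0)
  d <- sqrt(rowSums((c$xyz[pr$i, , drop = FALSE] -
                       c$xyz[pr$j, , drop = FALSE])^2))
  sum(pmax(0, pr$sigma - d)^2)
}

#' @keywords internal
.clash_pairs <- function(c) {
  a <- c$atoms
  n <- nrow(a)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_res <- a$peptide_id[i] == a$peptide_id[j] &
    a$residue_index[i] == a$residue_index[j]
  bb <- c("N", "CA", "C", "O")
  adj_bb <- a$peptide_id[i] == a$peptide_id[j] &
    abs(a$residue_index[i] - a$residue_index[j]) == 1L &
    a$atom_name[i] %in% bb & a$atom_name[j] %in% bb
  keep <- !(same_res | adj_bb)
  data.frame(i = i[keep], j = j[keep],
             sigma = 0.9 * (a$vdw_radius[i[keep]] + a$vdw_radius[j[keep]]))
}

#' Monte Carlo clash relief under a bead-RMSD constraint
#'
#' Metropolis Monte Carlo on the grafted structure, in two phases
#' mirroring the reconstruction procedure: rigid side-chain moves (small
#' rotation about the side-chain centroid plus a small translation),
#' then small single-atom backbone displacements. Any move that takes the
#' mapped bead positions further than `max_cg_rmsd` from the source beads
#' (no re-superposition) is rejected outright. The best-so-far clash
#' energy is non-increasing and the final energy never exceeds the
#' initial one.
#'
#' @param c grafted united-atom [conformation()].
#' @param cg source four-bead [conformation()].
#' @param max_cg_rmsd hard bead-RMSD bound, Angstrom (default 2.0).
#' @param seed RNG seed.
#' @param schedule list with `n_moves` (total proposed moves, default
#'   10000, split between the two phases), `step` (translation scale,
#'   Angstrom), `angle` (rotation scale, radians), `temperature`
#'   (Metropolis acceptance temperature, energy units).
#' @return the relaxed [conformation()] with attributes
#'   `initial_energy`, `final_energy`, `best_energy_trace` summary and
#'   `bead_rmsd`.
#' @export
relax_clashes <- function(c, cg, max_cg_rmsd = 2.0, seed = 1L,
                          schedule = list(n_moves = 10000, step = 0.2,
                                          angle = 0.3, temperature = 0.05)) {
  if (is.null(schedule$n_moves) || schedule$n_moves <= 0)
    stop("schedule must propose a positive number of moves")
  step <- if (is.null(schedule$step)) 0.2 else schedule$step
  ang <- if (is.null(schedule$angle)) 0.3 else schedule$angle
  temp <- if (is.null(schedule$temperature)) 0.05 else schedule$temperature
  a <- c$atoms
  src_beads <- .cg_bead_coords(cg)
  e_total <- clash_energy(c)
  e_init <- e_total
  best <- e_total
  pr <- .clash_pairs(c)
  # adjacency lists: pair rows touching each atom
  pair_rows_of <- vector("list", nrow(a))
  for (r in seq_len(nrow(pr))) {
    pair_rows_of[[pr$i[r]]] <- c(pair_rows_of[[pr$i[r]]], r)
    pair_rows_of[[pr$j[r]]] <- c(pair_rows_of[[pr$j[r]]], r)
  }
  pair_energy <- function(xyz, rows) {
    if (!length(rows)) return(0)
    d <- sqrt(rowSums((xyz[pr$i[rows], , drop = FALSE] -
                         xyz[pr$j[rows], , drop = FALSE])^2))
    sum(pmax(0, pr$sigma[rows] - d)^2)
  }
  res_key <- paste(a$peptide_id, a$residue_index)
  sc_mask <- !(a$atom_name %in% c("N", "CA", "C", "O", "OXT"))
  sc_res <- unique(res_key[sc_mask])
  bb_atoms <- which(!sc_mask)
  # bead bookkeeping for incremental RMSD: each N/CA/C atom is its own
  # bead, each residue's side-chain atom set maps to one centroid bead
  bead_members <- list()
  atom_bead <- rep(NA_integer_, nrow(a))
  for (pep in sort(unique(a$peptide_id))) {
    for (ri in sort(unique(a$residue_index[a$peptide_id == pep]))) {
      sel <- which(a$peptide_id == pep & a$residue_index == ri)
      for (nm in c("N", "CA", "C")) {
        k <- sel[a$atom_name[sel] == nm][1]
        bead_members[[length(bead_members) + 1L]] <- k
        atom_bead[k] <- length(bead_members)
      }
      sc <- sel[sc_mask[sel]]
      if (length(sc)) {
        bead_members[[length(bead_members) + 1L]] <- sc
        atom_bead[sc] <- length(bead_members)
      }
    }
  }
  n_beads <- length(bead_members)
  if (n_beads != nrow(src_beads)) stop("bead sets do not match")
  # chain-connectivity guard: CA atoms and their sequence neighbors
  ca_atoms <- which(a$atom_name == "CA")
  ca_neighbors <- lapply(seq_len(nrow(a)), function(k) integer(0))
  for (k in ca_atoms) {
    nb <- ca_atoms[a$peptide_id[ca_atoms] == a$peptide_id[k] &
                     abs(a$residue_index[ca_atoms] - a$residue_index[k]) == 1L]
    ca_neighbors[[k]] <- nb
  }
  bead_pos <- function(xyz, b) {
    mb <- bead_members[[b]]
    if (length(mb) == 1L) xyz[mb, ] else colMeans(xyz[mb, , drop = FALSE])
  }
  .with_seed(seed, {
    xyz <- c$xyz
    best_xyz <- xyz
    sq <- vapply(seq_len(n_beads), function(b)
      sum((bead_pos(xyz, b) - src_beads[b, ])^2), numeric(1))
    n_side <- if (length(sc_res)) ceiling(schedule$n_moves / 2) else 0L
    for (mv in seq_len(schedule$n_moves)) {
      if (mv <= n_side) {
        rk <- sample(sc_res, 1L)
        atoms_mv <- which(res_key == rk & sc_mask)
        ctr <- colMeans(xyz[atoms_mv, , drop = FALSE])
        rot <- .rotation_z_to(.runit())        # random axis frame
        theta <- stats::rnorm(1, sd = ang)
        Rz <- matrix(c(cos(theta), -sin(theta), 0,
                       sin(theta), cos(theta), 0,
                       0, 0, 1), 3, 3, byrow = TRUE)
        RR <- rot %*% Rz %*% t(rot)
        shift <- stats::rnorm(3, sd = step)
        newpos <- sweep(sweep(xyz[atoms_mv, , drop = FALSE], 2L, ctr) %*%
                          t(RR), 2L, ctr + shift, "+")
      } else {
        atoms_mv <- sample(bb_atoms, 1L)
        newpos <- xyz[atoms_mv, , drop = FALSE] +
          matrix(stats::rnorm(3, sd = step / 2), 1)
        # keep the Calpha trace connected (virtual bonds in 2.8-4.5 A)
        nb <- ca_neighbors[[atoms_mv]]
        if (length(nb)) {
          dd <- sqrt(rowSums(sweep(xyz[nb, , drop = FALSE], 2L,
                                   newpos[1, ])^2))
          if (any(dd < 2.8 | dd > 4.5)) next
        }
      }
      rows <- unique(unlist(pair_rows_of[atoms_mv], use.names = FALSE))
      e_old <- pair_energy(xyz, rows)
      xyz_new <- xyz
      xyz_new[atoms_mv, ] <- newpos
      e_new <- pair_energy(xyz_new, rows)
      dE <- e_new - e_old
      # strictly-zero-gain moves are rejected so already clash-free
      # structures pass through untouched
      if (dE == 0) next
      if (dE > 0 && stats::runif(1) >= exp(-dE / temp)) next
      touched <- unique(atom_bead[atoms_mv])
      touched <- touched[!is.na(touched)]
      sq_new <- sq
      for (b in touched)
        sq_new[b] <- sum((bead_pos(xyz_new, b) - src_beads[b, ])^2)
      if (sqrt(sum(sq_new) / n_beads) > max_cg_rmsd) next
      xyz <- xyz_new
      sq <- sq_new
      e_total <- e_total + dE
      if (e_total < best) { best <- e_total; best_xyz <- xyz }
    }
    # return the best structure seen (the input itself if nothing improved)
    out <- conformation(a, best_xyz, validate = FALSE)
    attr(out, "initial_energy") <- e_init
    attr(out, "final_energy") <- best
    attr(out, "best_energy") <- best
    attr(out, "bead_rmsd") <- bead_rmsd(out, cg)
    out
  })
}

#' Reconstruct a united-atom structure from a four-bead conformation
#'
#' Wrapper for the two reconstruction stages: side-chain template
#' grafting ([graft_side_chains()]) followed by Monte Carlo clash relief
#' ([relax_clashes()]). Returns the structure plus a reconstruction
#' report. Hydrogens can optionally be requested but placement is off by
#' default (delegating protonation to external tools is standard).
#'
#' @param cg four-bead [conformation()].
#' @param max_cg_rmsd bead-RMSD bound, Angstrom (default 2.0).
#' @param seed RNG seed for the Monte Carlo stage.
#' @param schedule Monte Carlo schedule, see [relax_clashes()].
#' @return list with `conformation` (united-atom) and `report` (data
#'   frame: initial/final clash energy, bead RMSD).
#' @export
reconstruct <- function(cg, max_cg_rmsd = 2.0, seed = 1L,
                        schedule = list(n_moves = 10000, step = 0.2,
                                        angle = 0.3, temperature = 0.05)) {
  grafted <- graft_side_chains(cg)
  relaxed <- relax_clashes(grafted, cg, max_cg_rmsd = max_cg_rmsd,
                           seed = seed, schedule = schedule)
  list(conformation = relaxed,
       report = data.frame(
         initial_energy = attr(relaxed, "initial_energy"),
         final_energy = attr(relaxed, "final_energy"),
         bead_rmsd = attr(relaxed, "bead_rmsd"),
         rmsd_bound = max_cg_rmsd,
         bound_satisfied = attr(relaxed, "bead_rmsd") <= max_cg_rmsd))
}
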