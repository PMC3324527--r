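# Seeded synthetic-ensemble generators. These stand in for MD trajectory
# data: they reproduce the statistical structure the analyses assume
# (self-avoiding chains, quasi-spherical dimers with buried C-termini,
# two-state salt-bridge dynamics, uniform water shells, four-bead chains)
# without any claim of physically realistic dynamics.

#' Generator configuration
#'
#' @param seed integer master seed; every generator derives per-trajectory
#'   seeds as `seed + trajectory index`, so trajectory subsets reproduce.
#' @param n_trajectories number of trajectories.
#' @param frames_per_trajectory frames per trajectory.
#' @param bond_length Calpha-Calpha virtual bond, Angstrom (default 3.8).
#' @param compactness target radius of gyration, Angstrom (`Inf` = no
#'   rescaling; chains keep their as-built size).
#' @param target_contact_number interpeptide Calpha contact target for
#'   dimer generation.
#' @param contact_cutoff Calpha contact cutoff used by the dimer
#'   generator's self-check, Angstrom (default 7.5).
#' @param saltbridge_spec data frame with columns `pos_residue`,
#'   `neg_residue`, `occupancy` (in `[0, 1]`) and `dwell` (mean dwell,
#'   frames) for the telegraph generator.
#' @param water_density water molecules per Angstrom^3 (bulk water is
#'   about 0.0334).
#' @param box_radius half-width of the cubic water box, Angstrom.
#' @param jitter_sd per-frame Gaussian coordinate jitter, Angstrom.
#' @param interval recording interval attached to generated ensembles, ps.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_trajectories = 1L,
                             frames_per_trajectory = 1L,
                             bond_length = 3.8, compactness = Inf,
                             target_contact_number = 20L,
                             contact_cutoff = 7.5,
                             saltbridge_spec = NULL,
                             water_density = 0.0334, box_radius = 25,
                             jitter_sd = 0.3, interval = 50) {
  if (bond_length <= 0) stop("bond_length must be positive")
  if (!is.null(saltbridge_spec)) {
    if (any(saltbridge_spec$occupancy < 0 | saltbridge_spec$occupancy > 1))
      stop("salt-bridge occupancy must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_trajectories = n_trajectories,
                 frames_per_trajectory = frames_per_trajectory,
                 bond_length = bond_length, compactness = compactness,
                 target_contact_number = target_contact_number,
                 contact_cutoff = contact_cutoff,
                 saltbridge_spec = saltbridge_spec,
                 water_density = water_density, box_radius = box_radius,
                 jitter_sd = jitter_sd, interval = interval),
            class = "generator_config")
}

#' Evaluate an expression with a temporary RNG seed
#' @keywords internal
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random unit vector
#' @keywords internal
.runit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Self-avoiding Calpha walk
#'
#' Sequential placement with rejection: each new Calpha sits at the bond
#' length from its predecessor and at least `min_sep` from every
#' non-adjacent Calpha. Optionally biased toward a per-step target
#' direction.
#'
#' @keywords internal
.saw_chain <- function(n, bond = 3.8, min_sep = 4.0, start = c(0, 0, 0),
                       bias_fun = NULL, max_restart = 50L) {
  for (attempt in seq_len(max_restart)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- start
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:200) {
        d <- .runit()
        if (!is.null(bias_fun)) {
          b <- bias_fun(i, xyz[i - 1, ])
          if (!is.null(b)) {
            d <- d + b
            d <- d / sqrt(sum(d^2))
          }
        }
        cand <- xyz[i - 1, ] + bond * d
        if (i > 2L) {
          d2 <- colSums((t(xyz[1:(i - 2), , drop = FALSE]) - cand)^2)
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("self-avoiding walk failed after ", max_restart, " restarts")
}

#' Atom table for a pseudo-atom peptide chain
#'
#' One CA bead per residue plus one side-chain pseudo-atom per non-Gly
#' residue. Side-chain pseudo-atoms of the charged residues carry the
#' N/O names needed by salt-bridge detection (NH1/NZ for R/K, OD1/OE1 for
#' D/E), so detection code runs unmodified on synthetic data.
#'
#' @keywords internal
.pseudo_atom_table <- function(spec, peptide_id = 1L) {
  codes <- strsplit(spec$sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(codes)) {
    rows[[length(rows) + 1L]] <-
      .atom_block(peptide_id, i, codes[i], "CA", "C")
    if (codes[i] != "G") {
      nm <- switch(codes[i], R = "NH1", K = "NZ", D = "OD1", E = "OE1", "CB")
      el <- switch(codes[i], R = "N", K = "N", D = "O", E = "O", "C")
      rows[[length(rows) + 1L]] <- .atom_block(peptide_id, i, codes[i], nm, el)
    }
  }
  do.call(rbind, rows)
}

#' Coordinates for a pseudo-atom chain given its Calpha trace
#' @keywords internal
.pseudo_coords <- function(ca, atoms) {
  cm <- colMeans(ca)
  xyz <- matrix(NA_real_, nrow(atoms), 3)
  for (k in seq_len(nrow(atoms))) {
    i <- atoms$residue_index[k]
    if (atoms$atom_name[k] == "CA") xyz[k, ] <- ca[i, ]
    else {
      out_dir <- ca[i, ] - cm
      nrm <- sqrt(sum(out_dir^2))
      if (nrm < 1e-8) out_dir <- c(1, 0, 0) else out_dir <- out_dir / nrm
      xyz[k, ] <- ca[i, ] + 2.0 * out_dir
    }
  }
  xyz
}

#' Rescale a frame about its center of mass to a target radius of gyration
#' @keywords internal
.rescale_rg <- function(xyz, mass, target) {
  cm <- colSums(xyz * mass) / sum(mass)
  cur <- sqrt(sum(mass * rowSums(sweep(xyz, 2L, cm)^2)) / sum(mass))
  sweep(sweep(xyz, 2L, cm) * (target / cur), 2L, cm, "+")
}

#' Generate a synthetic disordered-monomer ensemble
#'
#' Each trajectory gets one self-avoiding Calpha base walk (bond length
#' `cfg$bond_length`, non-adjacent pairs at least 4 Angstrom apart) with
#' one side-chain pseudo-atom per non-Gly residue. The first frame is the
#' unperturbed base chain; subsequent frames add Gaussian jitter
#' (`cfg$jitter_sd`). When `cfg$compactness` is finite every frame is
#' rescaled about its CM so the mass-weighted radius of gyration equals
#' the target exactly. Deterministic for a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @param spec an [alloform()] spec.
#' @return an [ensemble()].
#' @export
gen_monomer_ensemble <- function(cfg, spec = alloform("Ab42")) {
  if (cfg$frames_per_trajectory < 1L) stop("need at least one frame")
  n <- spec$length
  if (is.finite(cfg$compactness) && cfg$compactness < 1.8 * n^(1 / 3))
    stop("target radius of gyration below close-packing for ", n, " residues")
  atoms <- .pseudo_atom_table(spec)
  trajs <- lapply(seq_len(cfg$n_trajectories), function(ti) {
    .with_seed(cfg$seed + ti, {
      ca <- .saw_chain(n, bond = cfg$bond_length)
      base <- .pseudo_coords(ca, atoms)
      nf <- cfg$frames_per_trajectory
      arr <- array(0, dim = c(nrow(atoms), 3L, nf))
      for (f in seq_len(nf)) {
        xyz <- base
        if (f > 1L)
          xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = cfg$jitter_sd),
                              ncol = 3)
        if (is.finite(cfg$compactness))
          xyz <- .rescale_rg(xyz, atoms$mass, cfg$compactness)
        arr[, , f] <- xyz
      }
      list(times = cfg$interval * seq_len(nf), xyz = arr)
    })
  })
  ensemble(atoms, trajs, interval = cfg$interval)
}

#' Generate a synthetic dimer ensemble
#'
#' Two peptide chains are built as inward-directed self-avoiding walks
#' starting from opposite sides of the assembly, so residues 30 to the
#' C-terminus end up near the assembly center while residues 1-5 stay on
#' the outside (solvent-exposed N-termini, buried C-termini, the
#' quasi-spherical arrangement typical of amyloid-beta dimers). For every
#' frame the second chain is slid along the assembly axis until the
#' interpeptide Calpha contact number at `cfg$contact_cutoff` lies within
#' `cfg$target_contact_number +/- 2`; an error is raised when no
#' separation achieves the target.
#'
#' @param cfg a [generator_config()].
#' @param spec an [alloform()] spec.
#' @return an [ensemble()] with two peptides.
#' @export
gen_dimer_ensemble <- function(cfg, spec = alloform("Ab42")) {
  if (cfg$target_contact_number < 0) stop("target contact number must be >= 0")
  n <- spec$length
  if (cfg$target_contact_number > n * n)
    stop("contact target infeasible for chain length ", n)
  atoms <- rbind(.pseudo_atom_table(spec, 1L), .pseudo_atom_table(spec, 2L))
  r0 <- 25
  # inward pull toward the assembly center while the chain is still far
  # out, so the C-terminal third ends up buried near the center while the
  # N-terminus stays outside; once near the core the walk is unbiased
  bias <- function(sign_x) function(i, prev) {
    nrm <- sqrt(sum(prev^2))
    if (nrm > 8) 0.9 * (-prev) / nrm else NULL
  }
  trajs <- lapply(seq_len(cfg$n_trajectories), function(ti) {
    .with_seed(cfg$seed + ti, {
      nf <- cfg$frames_per_trajectory
      arr <- array(0, dim = c(nrow(atoms), 3L, nf))
      for (f in seq_len(nf)) {
        done <- FALSE
        for (attempt in 1:20) {
          ca1 <- .saw_chain(n, bond = cfg$bond_length,
                            start = c(r0, 0, 0), bias_fun = bias(+1))
          ca2 <- .saw_chain(n, bond = cfg$bond_length,
                            start = c(-r0, 0, 0), bias_fun = bias(-1))
          adj <- .tune_separation(ca1, ca2, cfg$target_contact_number,
                                  cfg$contact_cutoff)
          if (!is.null(adj)) { ca2 <- adj; done <- TRUE; break }
        }
        if (!done)
          stop("contact target ", cfg$target_contact_number,
               " infeasible for chain length ", n)
        xyz1 <- .pseudo_coords(ca1, atoms[atoms$peptide_id == 1L, ])
        xyz2 <- .pseudo_coords(ca2, atoms[atoms$peptide_id == 2L, ])
        arr[, , f] <- rbind(xyz1, xyz2)
      }
      list(times = cfg$interval * seq_len(nf), xyz = arr)
    })
  })
  ensemble(atoms, trajs, interval = cfg$interval)
}

#' Slide chain 2 along x until the contact count enters the target band
#' @keywords internal
.tune_separation <- function(ca1, ca2, target, cutoff) {
  count_at <- function(s) {
    shifted <- sweep(ca2, 2L, c(s, 0, 0), "-")
    sum(.cross_dist2(ca1, shifted) < cutoff^2)
  }
  if (target == 0) {
    # push far out, then verify
    for (s in seq(-60, -200, by = -20)) if (count_at(s) == 0)
      return(sweep(ca2, 2L, c(s, 0, 0), "-"))
    return(NULL)
  }
  for (s in seq(-30, 70, by = 0.25)) {
    k <- count_at(s)
    if (abs(k - target) <= 2)
      return(sweep(ca2, 2L, c(s, 0, 0), "-"))
  }
  NULL
}

#' Impose two-state (telegraph) salt-bridge dynamics on an ensemble
#'
#' For every pair in `cfg$saltbridge_spec` a two-state Markov chain with
#' stationary occupancy `p` and mean ON dwell `dwell` frames is simulated
#' per trajectory. In ON frames the positive residue's side-chain N
#' pseudo-atom is moved to `cutoff - 1` Angstrom from the negative
#' residue's side-chain O; in OFF frames to `cutoff + 3`. On dimers the
#' chain is applied to peptide 1 and the same pair on other peptides is
#' held OFF, so the pooled intrapeptide propensity recovers `p`.
#'
#' @param cfg a [generator_config()] with a `saltbridge_spec`.
#' @param base an [ensemble()] whose topology carries the needed
#'   side-chain N/O pseudo-atoms.
#' @param cutoff detection cutoff the dynamics are built around,
#'   Angstrom (default 4.0).
#' @return the modified [ensemble()].
#' @export
gen_saltbridge_telegraph <- function(cfg, base, cutoff = 4.0) {
  sb <- cfg$saltbridge_spec
  if (is.null(sb) || !nrow(sb)) stop("cfg$saltbridge_spec is empty")
  if (any(sb$occupancy < 0 | sb$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  top <- base$topology
  peps <- sort(unique(top$peptide_id))
  for (ti in seq_along(base$trajectories)) {
    tr <- base$trajectories[[ti]]
    nf <- length(tr$times)
    base$trajectories[[ti]]$xyz <- .with_seed(cfg$seed + 1000L + ti, {
      arr <- tr$xyz
      for (r in seq_len(nrow(sb))) {
        p <- sb$occupancy[r]
        dwell <- if (!is.null(sb$dwell)) sb$dwell[r] else 10
        states <- .telegraph_states(nf, p, dwell)
        ni <- which(top$peptide_id == 1L & top$residue_index == sb$pos_residue[r] &
                      top$element == "N" & top$atom_name != "N")
        oi <- which(top$peptide_id == 1L & top$residue_index == sb$neg_residue[r] &
                      top$element == "O" & top$atom_name != "O")
        if (!length(ni) || !length(oi))
          stop("pair ", sb$pos_residue[r], "-", sb$neg_residue[r],
               ": missing side-chain N/O pseudo-atoms")
        for (f in seq_len(nf)) {
          d_target <- if (states[f]) cutoff - 1 else cutoff + 3
          arr[ni[1], , f] <- .place_at_distance(arr[oi[1], , f],
                                                arr[ni[1], , f], d_target)
        }
        for (pp in setdiff(peps, 1L)) {
          ni2 <- which(top$peptide_id == pp &
                         top$residue_index == sb$pos_residue[r] &
                         top$element == "N" & top$atom_name != "N")
          oi2 <- which(top$peptide_id == pp &
                         top$residue_index == sb$neg_residue[r] &
                         top$element == "O" & top$atom_name != "O")
          for (f in seq_len(nf))
            arr[ni2[1], , f] <- .place_at_distance(arr[oi2[1], , f],
                                                   arr[ni2[1], , f],
                                                   cutoff + 3)
        }
      }
      arr
    })
  }
  base
}

#' @keywords internal
.place_at_distance <- function(anchor, current, d) {
  dir <- current - anchor
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-8) dir <- c(1, 0, 0) else dir <- dir / nrm
  anchor + d * dir
}

#' Two-state Markov chain with stationary occupancy p and mean ON dwell
#' @keywords internal
.telegraph_states <- function(nf, p, dwell) {
  if (p <= 0) return(rep(FALSE, nf))
  if (p >= 1) return(rep(TRUE, nf))
  q_off <- min(1, 1 / dwell)             # ON -> OFF
  q_on <- min(1, q_off * p / (1 - p))    # OFF -> ON (stationarity)
  s <- logical(nf)
  s[1] <- stats::runif(1) < p
  for (f in 2:nf) {
    s[f] <- if (s[f - 1]) stats::runif(1) >= q_off else stats::runif(1) < q_on
  }
  s
}

#' Generate a uniform-density water shell around a solute
#'
#' Water oxygens are drawn as a Poisson point process of intensity
#' `cfg$water_density` in the cube of half-width `cfg$box_radius`
#' centered on the solute CM; positions within 2.6 Angstrom of any solute
#' heavy atom are rejected, carving out the excluded volume.
#'
#' @param cfg a [generator_config()].
#' @param solute a [conformation()], or NULL for pure bulk water.
#' @param seed_offset added to `cfg$seed` (vary per frame).
#' @return n x 3 matrix of water oxygen coordinates.
#' @export
gen_water_shell <- function(cfg, solute = NULL, seed_offset = 0L) {
  rho <- cfg$water_density
  if (rho < 0) stop("water_density must be >= 0")
  if (rho == 0) return(matrix(numeric(0), 0, 3))
  R <- cfg$box_radius
  V <- (2 * R)^3
  lambda <- rho * V
  if (lambda > 5e6) stop("water density too high: ", lambda,
                         " expected molecules will not terminate")
  center <- if (is.null(solute)) c(0, 0, 0) else center_of_mass(solute)
  .with_seed(cfg$seed + seed_offset, {
    n <- stats::rpois(1, lambda)
    pts <- matrix(stats::runif(3 * n, -R, R), ncol = 3)
    pts <- sweep(pts, 2L, center, "+")
    if (!is.null(solute)) {
      heavy <- solute$atoms$element != "H"
      d2 <- .cross_dist2(pts, solute$xyz[heavy, , drop = FALSE])
      pts <- pts[apply(d2, 1L, min) >= 2.6^2, , drop = FALSE]
    }
    pts
  })
}

#' Generate a four-bead coarse-grained conformer
#'
#' Per residue: N, CA and C backbone beads with idealized local geometry
#' on a self-avoiding Calpha trace, plus one side-chain bead (named CB) at
#' 2 Angstrom from the Calpha, absent for glycine. This is the input
#' surrogate for the coarse-grained reconstruction stage.
#'
#' @param cfg a [generator_config()].
#' @param spec an [alloform()] spec (or any sequence via `sequence`).
#' @param sequence optional one-letter sequence overriding `spec`.
#' @param min_sep minimal non-adjacent Calpha separation, Angstrom
#'   (default 4.0; larger values yield more open chains whose backbone
#'   beads are clash-free after grafting).
#' @return a four-bead [conformation()].
#' @export
gen_cg_conformer <- function(cfg, spec = alloform("Ab42"), sequence = NULL,
                             min_sep = 4.0) {
  codes <- if (is.null(sequence)) strsplit(spec$sequence, "")[[1]]
           else strsplit(sequence, "")[[1]]
  n <- length(codes)
  .with_seed(cfg$seed, {
    ca <- .saw_chain(n, bond = cfg$bond_length, min_sep = min_sep)
    cm <- colMeans(ca)
    rows <- list(); coords <- list()
    for (i in seq_len(n)) {
      to_prev <- if (i > 1L) ca[i - 1, ] - ca[i, ] else .runit()
      to_next <- if (i < n) ca[i + 1, ] - ca[i, ] else .runit()
      unit <- function(v) v / sqrt(sum(v^2))
      rows[[length(rows) + 1L]] <- .atom_block(1L, i, codes[i], "N", "N")
      coords[[length(coords) + 1L]] <- ca[i, ] + 1.46 * unit(to_prev)
      rows[[length(rows) + 1L]] <- .atom_block(1L, i, codes[i], "CA", "C")
      coords[[length(coords) + 1L]] <- ca[i, ]
      rows[[length(rows) + 1L]] <- .atom_block(1L, i, codes[i], "C", "C")
      coords[[length(coords) + 1L]] <- ca[i, ] + 1.52 * unit(to_next)
      if (codes[i] != "G") {
        out_dir <- ca[i, ] - cm
        nrm <- sqrt(sum(out_dir^2))
        out_dir <- if (nrm < 1e-8) c(0, 0, 1) else out_dir / nrm
        rows[[length(rows) + 1L]] <- .atom_block(1L, i, codes[i], "CB", "C")
        coords[[length(coords) + 1L]] <- ca[i, ] + 2.0 * out_dir
      }
    }
    conformation(do.call(rbind, rows), do.call(rbind, coords))
  })
}
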