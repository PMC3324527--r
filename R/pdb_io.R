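# PDB and trajectory I/O, built on bio3d for record parsing/writing.

#' Read a structure file into a conformation
#'
#' Chains are mapped to peptide ids in order of first appearance (chain A
#' becomes peptide 1, chain B peptide 2). Atoms are decorated with
#' element-derived van der Waals radii and masses from the package's fixed
#' internal table, so downstream results are installation-independent.
#' Water and ion records are dropped; use [load_waters()] for solvent.
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is currently supported.
#' @param spec optional [alloform()] spec; when supplied, residue identities
#'   are validated against the alloform sequence.
#' @return a [conformation()].
#' @export
load_structure <- function(path, format = "pdb", spec = NULL) {
  format <- match.arg(format, "pdb")
  .check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  .conformation_from_bio3d(pdb$atom, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE),
                           spec = spec)
}

#' @keywords internal
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed PDB record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("malformed PDB record at line ", i, ": unparsable coordinates")
  }
  invisible(TRUE)
}

.water_resids <- c("HOH", "SOL", "WAT", "TIP", "SPC")
.ion_resids <- c("NA", "CL", "NA+", "CL-", "SOD", "CLA")

#' @keywords internal
.conformation_from_bio3d <- function(atom, xyz1, spec = NULL, frame_time = 0) {
  keep <- !(atom$resid %in% c(.water_resids, .ion_resids))
  atom <- atom[keep, , drop = FALSE]
  xyz1 <- xyz1[keep, , drop = FALSE]
  chain <- atom$chain
  chain[is.na(chain) | chain == ""] <- "A"
  pep <- as.integer(factor(chain, levels = unique(chain)))
  code <- aa_one(atom$resid)   # errors on unknown residue names
  elem <- atom$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- element_from_atom_name(atom$elety[bad])
  atoms <- .atom_block(pep, atom$resno, code, trimws(atom$elety), toupper(elem))
  if (!is.null(spec)) {
    idx <- atoms$residue_index
    if (any(idx > spec$length))
      stop("residue index beyond ", spec$name, " length ", spec$length)
    want <- substring(spec$sequence, idx, idx)
    mism <- which(atoms$residue_code != want)
    if (length(mism))
      stop("residue identity mismatch with ", spec$name, " at position(s) ",
           paste(unique(idx[mism]), collapse = ", "))
  }
  conformation(atoms, xyz1, frame_time = frame_time)
}

#' Write a conformation as a PDB file
#'
#' One chain per peptide (A, B). Coordinates are written at the standard
#' PDB precision (0.001 Angstrom).
#'
#' @param c a [conformation()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(c, path) {
  a <- c$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(c$xyz)),
                   resno = a$residue_index,
                   resid = aa_three(a$residue_code),
                   elety = a$atom_name,
                   chain = LETTERS[a$peptide_id],
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Read water oxygen coordinates from a PDB file
#'
#' @param path PDB file path.
#' @return numeric matrix (n x 3) of water oxygen positions, Angstrom.
#' @export
load_waters <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- pdb$atom$resid %in% .water_resids & pdb$atom$elety %in% c("O", "OW", "OH2")
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  xyz[sel, , drop = FALSE]
}

#' Load a trajectory into an ensemble
#'
#' The trajectory may be a multi-model PDB or a DCD file. Frame times are
#' `interval, 2*interval, ...` unless given explicitly; frames outside the
#' half-open analysis window `(t_start, t_end]` are dropped.
#'
#' @param topology PDB file defining the atom table.
#' @param trajectory trajectory file (multi-model PDB or DCD), or a list of
#'   such files (one per trajectory).
#' @param window analysis window `(t_start, t_end]` in ps.
#' @param interval recording interval in ps.
#' @param times optional explicit frame times (ps) per trajectory.
#' @param spec optional [alloform()] spec for residue validation.
#' @return an [ensemble()].
#' @export
load_ensemble <- function(topology, trajectory, window, interval,
                          times = NULL, spec = NULL) {
  top <- load_structure(topology, spec = spec)
  files <- if (is.character(trajectory)) as.list(trajectory) else trajectory
  trajs <- lapply(seq_along(files), function(i) {
    xyz <- .read_traj_coords(files[[i]], n_atoms_expected = nrow(top$atoms))
    nf <- dim(xyz)[3]
    tt <- if (is.null(times)) interval * seq_len(nf) else times[[i]]
    if (length(tt) != nf)
      stop("trajectory ", i, ": frame count ", nf,
           " inconsistent with supplied times/interval")
    list(times = tt, xyz = xyz)
  })
  span <- range(unlist(lapply(trajs, `[[`, "times")))
  if (window[1] >= span[2] && window[1] != window[2])
    stop("analysis window starts beyond the trajectory span")
  ensemble(top$atoms, trajs, interval = interval, window = window)
}

#' @keywords internal
.read_traj_coords <- function(path, n_atoms_expected) {
  is_dcd <- grepl("\\.dcd$", path, ignore.case = TRUE)
  if (is_dcd) {
    m <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    m <- pdb$xyz
    keep <- !(pdb$atom$resid %in% c(.water_resids, .ion_resids))
    if (!all(keep)) {
      cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                              3 * which(keep)))
      m <- m[, cols, drop = FALSE]
    }
  }
  n_at <- ncol(m) / 3
  if (n_at != n_atoms_expected)
    stop("trajectory atom count (", n_at, ") does not match topology (",
         n_atoms_expected, ")")
  arr <- array(0, dim = c(n_at, 3L, nrow(m)))
  for (f in seq_len(nrow(m)))
    arr[, , f] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
  arr
}

#' Write an ensemble as a multi-model PDB trajectory
#'
#' @param e an [ensemble()].
#' @param path output path; one file, MODEL/ENDMDL separated, all
#'   trajectories concatenated in order.
#' @return invisibly, `path`.
#' @export
write_ensemble_pdb <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- e$topology
  model <- 0L
  for (tr in e$trajectories) {
    for (f in seq_along(tr$times)) {
      model <- model + 1L
      writeLines(sprintf("MODEL     %4d", model), con)
      xyz <- tr$xyz[, , f]
      nm <- a$atom_name
      nm4 <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), substr(nm, 1, 4))
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(a)), nm4, aa_three(a$residue_code),
        LETTERS[a$peptide_id], a$residue_index,
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
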