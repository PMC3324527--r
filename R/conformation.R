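#' Construct a conformation (one frame of an assembly)
#'
#' The basic container for a single structure: an atom table plus an
#' `n x 3` coordinate matrix in Angstrom. Monomers carry `peptide_id = 1`
#' for every atom; dimers use peptide ids 1 and 2.
#'
#' @param atoms data frame with columns `peptide_id` (integer), `residue_index`
#'   (1-based integer), `residue_code` (one-letter), `atom_name`, `element`,
#'   `vdw_radius` (Angstrom), `mass` (amu).
#' @param xyz numeric matrix, `nrow(atoms)` rows by 3 columns, Angstrom.
#' @param frame_time time stamp in ps (default 0).
#' @param validate run invariant checks (default TRUE).
#' @return object of class `conformation`.
#' @export
conformation <- function(atoms, xyz, frame_time = 0, validate = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  obj <- structure(list(atoms = atoms, xyz = xyz, frame_time = frame_time),
                   class = "conformation")
  if (validate) validate_conformation(obj)
  obj
}

#' Check conformation invariants
#'
#' Residue indices must lie in 1..42, every residue must have a Calpha (or
#' Calpha bead `CA`), coordinates must be finite, and peptide ids must be
#' `{1}` (monomer) or `{1, 2}` (dimer).
#'
#' @param c a `conformation`.
#' @return invisibly TRUE; stops with a message on violation.
#' @export
validate_conformation <- function(c) {
  a <- c$atoms
  need <- c("peptide_id", "residue_index", "residue_code", "atom_name",
            "element", "vdw_radius", "mass")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("atom table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(a) != nrow(c$xyz) || ncol(c$xyz) != 3L)
    stop("coordinate matrix must be nrow(atoms) x 3")
  if (!all(is.finite(c$xyz))) stop("non-finite coordinates")
  if (any(a$residue_index < 1L | a$residue_index > 42L))
    stop("residue_index outside 1..42")
  peps <- sort(unique(a$peptide_id))
  if (!identical(peps, 1L) && !identical(peps, c(1L, 2L)))
    stop("peptide_id must be {1} (monomer) or {1,2} (dimer)")
  for (p in peps) {
    sel <- a$peptide_id == p
    res <- unique(a$residue_index[sel])
    has_ca <- unique(a$residue_index[sel & a$atom_name == "CA"])
    lacking <- setdiff(res, has_ca)
    if (length(lacking))
      stop("peptide ", p, ": residue(s) without CA atom: ",
           paste(lacking, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.conformation <- function(x, ...) {
  np <- length(unique(x$atoms$peptide_id))
  cat("conformation:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$peptide_id, x$atoms$residue_index))),
      "residues,", np, if (np == 1L) "peptide" else "peptides",
      sprintf("(t = %g ps)\n", x$frame_time))
  invisible(x)
}

#' Number of peptides in a conformation
#' @param c a `conformation`.
#' @return integer 1 or 2.
#' @export
n_peptides <- function(c) length(unique(c$atoms$peptide_id))

#' Is the conformation a dimer?
#' @param c a `conformation`.
#' @return logical.
#' @export
is_dimer <- function(c) n_peptides(c) == 2L

#' Calpha coordinates of one peptide
#' @param c a `conformation`.
#' @param peptide peptide id (default 1).
#' @return matrix of Calpha coordinates ordered by residue index, with
#'   residue indices as rownames.
#' @export
calpha_coords <- function(c, peptide = 1L) {
  sel <- c$atoms$peptide_id == peptide & c$atoms$atom_name == "CA"
  ord <- order(c$atoms$residue_index[sel])
  out <- c$xyz[sel, , drop = FALSE][ord, , drop = FALSE]
  rownames(out) <- c$atoms$residue_index[sel][ord]
  out
}

#' Apply a rigid-body motion to a conformation
#' @param c a `conformation`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift, Angstrom.
#' @return transformed `conformation`.
#' @export
transform_conformation <- function(c, rotation = diag(3), translation = c(0, 0, 0)) {
  c$xyz <- sweep(c$xyz %*% t(rotation), 2L, translation, "+")
  c
}

#' Build an atom table row block for one residue
#' @keywords internal
.atom_block <- function(peptide_id, residue_index, residue_code, atom_name,
                        element) {
  props <- element_properties(element)
  data.frame(peptide_id = as.integer(peptide_id),
             residue_index = as.integer(residue_index),
             residue_code = residue_code,
             atom_name = atom_name,
             element = element,
             vdw_radius = props$vdw_radius,
             mass = props$mass,
             stringsAsFactors = FALSE)
}
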