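# Fixed internal element tables so results never depend on the installation.

#' Element van der Waals radii and atomic masses
#'
#' Internal constants used to decorate atoms read from PDB files or built by
#' the synthetic generators. Radii are the Bondi set commonly used for
#' solvent-accessibility calculations; masses are standard atomic weights.
#'
#' @format A data frame with columns `element`, `vdw_radius` (Angstrom) and
#'   `mass` (amu).
#' @keywords internal
.element_table <- data.frame(
  element    = c("H",    "C",    "N",    "O",    "S",    "P",    "NA",   "CL"),
  vdw_radius = c(1.20,   1.70,   1.55,   1.52,   1.80,   1.80,   2.27,   1.75),
  mass       = c(1.008, 12.011, 14.007, 15.999, 32.06,  30.974, 22.990, 35.45),
  stringsAsFactors = FALSE
)

#' Look up van der Waals radius and mass for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return data frame with columns `vdw_radius` and `mass`, one row per input.
#' @keywords internal
element_properties <- function(element) {
  idx <- match(toupper(element), .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .element_table[idx, c("vdw_radius", "mass"), drop = FALSE]
}

# One- to three-letter amino-acid code maps (20 standard residues).
.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Convert between one- and three-letter residue codes
#' @param x character vector of codes.
#' @return character vector of converted codes.
#' @keywords internal
aa_three <- function(x) {
  idx <- match(toupper(x), .aa1)
  if (anyNA(idx)) stop("unknown residue code(s): ",
                       paste(unique(x[is.na(idx)]), collapse = ", "))
  .aa3[idx]
}

#' @rdname aa_three
#' @keywords internal
aa_one <- function(x) {
  idx <- match(toupper(x), .aa3)
  if (anyNA(idx)) stop("unknown residue name(s): ",
                       paste(unique(x[is.na(idx)]), collapse = ", "))
  .aa1[idx]
}

# Side-chain heavy-atom templates: atom names and elements for the
# united-atom (heavy atoms only) representation of each residue.
# Glycine has an empty side chain.
.sidechain_atoms <- list(
  G = character(0),
  A = c("CB"),
  S = c("CB","OG"),
  C = c("CB","SG"),
  T = c("CB","OG1","CG2"),
  V = c("CB","CG1","CG2"),
  P = c("CB","CG","CD"),
  L = c("CB","CG","CD1","CD2"),
  I = c("CB","CG1","CG2","CD1"),
  M = c("CB","CG","SD","CE"),
  N = c("CB","CG","OD1","ND2"),
  D = c("CB","CG","OD1","OD2"),
  K = c("CB","CG","CD","CE","NZ"),
  Q = c("CB","CG","CD","OE1","NE2"),
  E = c("CB","CG","CD","OE1","OE2"),
  H = c("CB","CG","ND1","CD2","CE1","NE2"),
  F = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
  R = c("CB","CG","CD","NE","CZ","NH1","NH2"),
  Y = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
  W = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2")
)

#' Side-chain heavy atoms of a residue (united-atom representation)
#'
#' @param residue_code one-letter residue code.
#' @return character vector of side-chain heavy-atom names (empty for Gly).
#' @keywords internal
sidechain_atom_names <- function(residue_code) {
  out <- .sidechain_atoms[[toupper(residue_code)]]
  if (is.null(out)) stop("unknown residue code: ", residue_code)
  out
}

#' Infer the element from a PDB atom name
#'
#' First character after stripping digits; handles the standard protein
#' heavy atoms plus hydrogens.
#' @param atom_name character vector of PDB atom names.
#' @return character vector of element symbols.
#' @keywords internal
element_from_atom_name <- function(atom_name) {
  lead <- sub("^[0-9]*", "", trimws(atom_name))
  substr(lead, 1L, 1L)
}
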