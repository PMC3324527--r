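#' Amyloid-beta alloform registry
#'
#' Returns the sequence and charged/hydrophobic residue sets for the two
#' predominant amyloid beta-protein alloforms. Abeta42 is
#' `DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA` (42 residues, D1...A42);
#' Abeta40 is the same sequence without the two C-terminal residues I41-A42.
#' At neutral pH three residues are positively charged (R5, K16, K28) and six
#' negatively charged (D1, E3, D7, E11, E22, D23); each positive residue can
#' form a salt bridge with each negative one.
#'
#' The hydrophobic set defaults to residues of type A, V, L, I, M, F;
#' glycine and tyrosine are excluded as the conservative standard choice.
#'
#' @param name `"Ab40"` or `"Ab42"`.
#' @param hydrophobic_types one-letter residue types counted as hydrophobic.
#' @return An object of class `alloform_spec`: list with `name`, `sequence`
#'   (one-letter string), `length`, `positive_residues`, `negative_residues`
#'   and `hydrophobic_residues` (1-based residue indices).
#' @examples
#' ab42 <- alloform("Ab42")
#' ab42$positive_residues  # R5, K16, K28
#' @export
alloform <- function(name, hydrophobic_types = c("A", "V", "L", "I", "M", "F")) {
  seq42 <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("Ab40", "Ab42")) {
    stop("unknown alloform: ", paste(name, collapse = ","),
         " (expected \"Ab40\" or \"Ab42\")")
  }
  sq <- if (name == "Ab42") seq42 else substr(seq42, 1L, 40L)
  n <- nchar(sq)
  letters1 <- strsplit(sq, "")[[1]]
  spec <- list(
    name = name,
    sequence = sq,
    length = n,
    positive_residues = c(R5 = 5L, K16 = 16L, K28 = 28L),
    negative_residues = c(D1 = 1L, E3 = 3L, D7 = 7L, E11 = 11L,
                          E22 = 22L, D23 = 23L),
    hydrophobic_residues = which(letters1 %in% hydrophobic_types)
  )
  class(spec) <- "alloform_spec"
  spec
}

#' @export
print.alloform_spec <- function(x, ...) {
  cat("Amyloid-beta alloform:", x$name, "(", x$length, "residues )\n")
  cat("  sequence:   ", x$sequence, "\n")
  cat("  positive:   ", paste(names(x$positive_residues), collapse = ", "), "\n")
  cat("  negative:   ", paste(names(x$negative_residues), collapse = ", "), "\n")
  cat("  hydrophobic:", length(x$hydrophobic_residues), "residues\n")
  invisible(x)
}

#' Label a charged residue like "R5" or "D1"
#' @param spec an `alloform_spec`.
#' @param index residue index.
#' @return character label: one-letter code followed by index.
#' @keywords internal
residue_label <- function(spec, index) {
  paste0(substring(spec$sequence, index, index), index)
}
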