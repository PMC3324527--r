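# Salt-bridge detection, propensities, and propensity-table assembly.

#' Detect salt bridges in one conformation
#'
#' A salt bridge between a positively charged residue (R5, K16, K28) and a
#' negatively charged residue (D1, E3, D7, E11, E22, D23) is present
#' whenever any side-chain nitrogen atom of the positive residue lies
#' strictly within `cutoff` of any side-chain oxygen atom of the negative
#' residue. Backbone N/O and the charged termini are excluded: the tables
#' this feeds enumerate side-chain pairs only.
#'
#' @param c a [conformation()].
#' @param cutoff N-O distance cutoff, Angstrom (default 4.0; a standard
#'   salt-bridge criterion, configurable).
#' @param spec an [alloform()] spec naming the charged residues.
#' @return data frame with columns `pos_residue`, `neg_residue`
#'   (residue indices), `pos_peptide`, `neg_peptide`, `min_distance`.
#' @export
detect_salt_bridges <- function(c, cutoff = 4.0, spec = alloform("Ab42")) {
  a <- c$atoms
  sc_n <- a$element == "N" & a$atom_name != "N"
  sc_o <- a$element == "O" & !(a$atom_name %in% c("O", "OXT", "OT1", "OT2"))
  peps <- sort(unique(a$peptide_id))
  out <- list()
  for (pp in peps) for (np in peps) {
    for (pr in spec$positive_residues) {
      ni <- which(sc_n & a$peptide_id == pp & a$residue_index == pr)
      if (!length(ni))
        stop("missing side-chain N atoms for positive residue ",
             residue_label(spec, pr), " (peptide ", pp, ")")
      for (nr in spec$negative_residues) {
        oi <- which(sc_o & a$peptide_id == np & a$residue_index == nr)
        if (!length(oi))
          stop("missing side-chain O atoms for negative residue ",
               residue_label(spec, nr), " (peptide ", np, ")")
        d2 <- .cross_dist2(c$xyz[ni, , drop = FALSE],
                           c$xyz[oi, , drop = FALSE])
        dmin <- sqrt(min(d2))
        if (dmin < cutoff)
          out[[length(out) + 1L]] <- data.frame(
            pos_residue = pr, neg_residue = nr,
            pos_peptide = pp, neg_peptide = np, min_distance = dmin)
      }
    }
  }
  if (!length(out))
    return(data.frame(pos_residue = integer(0), neg_residue = integer(0),
                      pos_peptide = integer(0), neg_peptide = integer(0),
                      min_distance = numeric(0)))
  do.call(rbind, out)
}

#' Salt-bridge propensities of an ensemble
#'
#' Propensity = 100 x (frames in which the bridge is present) / (frames
#' observed), computed per trajectory and then averaged across trajectories;
#' the SEM is the standard error of the trajectory means. A bridge is
#' intrapeptide when both partners sit on the same peptide (occurrences on
#' either peptide of a dimer pool into one statistic) and interpeptide
#' otherwise. For monomers interpeptide propensities are structurally
#' absent and reported as `NA`, not 0.
#'
#' @param e an [ensemble()].
#' @param cutoff N-O cutoff, Angstrom (default 4.0).
#' @param spec an [alloform()] spec.
#' @return data frame with one row per (positive, negative) pair: columns
#'   `pair`, `pos_residue`, `neg_residue`, `intra`, `intra_sem`, `inter`,
#'   `inter_sem`, `total`, `total_sem` (percent).
#' @export
saltbridge_propensity <- function(e, cutoff = 4.0, spec = alloform("Ab42")) {
  dimer <- length(unique(e$topology$peptide_id)) == 2L
  pos <- spec$positive_residues
  neg <- spec$negative_residues
  pair_key <- function(p, n) paste(p, n, sep = "-")
  keys <- as.vector(outer(pos, neg, pair_key))
  per_traj_intra <- matrix(0, length(keys), n_trajectories(e),
                           dimnames = list(keys, NULL))
  per_traj_inter <- per_traj_intra
  for (ti in seq_len(n_trajectories(e))) {
    nf <- length(e$trajectories[[ti]]$times)
    for (f in seq_len(nf)) {
      det <- detect_salt_bridges(get_frame(e, ti, f), cutoff = cutoff,
                                 spec = spec)
      if (!nrow(det)) next
      k <- pair_key(det$pos_residue, det$neg_residue)
      intra <- det$pos_peptide == det$neg_peptide
      # presence per frame: pooled over peptides, counted once per pair
      for (kk in unique(k[intra]))
        per_traj_intra[kk, ti] <- per_traj_intra[kk, ti] + 1
      for (kk in unique(k[!intra]))
        per_traj_inter[kk, ti] <- per_traj_inter[kk, ti] + 1
      }
    per_traj_intra[, ti] <- 100 * per_traj_intra[, ti] / nf
    per_traj_inter[, ti] <- 100 * per_traj_inter[, ti] / nf
  }
  ms_intra <- .rowwise_mean_sem(per_traj_intra)
  ms_inter <- .rowwise_mean_sem(per_traj_inter)
  ms_total <- .rowwise_mean_sem(per_traj_intra + per_traj_inter)
  grid <- expand.grid(pos = pos, neg = neg)
  data.frame(
    pair = paste0(residue_label(spec, grid$pos), "-",
                  residue_label(spec, grid$neg)),
    pos_residue = grid$pos, neg_residue = grid$neg,
    intra = ms_intra$mean, intra_sem = ms_intra$sem,
    inter = if (dimer) ms_inter$mean else NA_real_,
    inter_sem = if (dimer) ms_inter$sem else NA_real_,
    total = if (dimer) ms_total$mean else ms_intra$mean,
    total_sem = if (dimer) ms_total$sem else ms_intra$sem,
    row.names = NULL)
}

#' Round half away from zero (table display convention)
#' @param x numeric.
#' @return numeric rounded to integers, halves up.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Aggregate per-pair salt-bridge propensities into a propensity table
#'
#' Builds the standard propensity-table layout: six pair rows per positive
#' residue, a `TOTAL` row per positive residue (the column sum of its six
#' pair rows; totals may exceed 100% because the six bridges are not
#' mutually exclusive), and a final `Average TOTAL` row (the mean of the
#' three TOTAL rows). Aggregates are computed from unrounded values and
#' only rounded for display (round-half-up).
#'
#' @param per_pair data frame as returned by [saltbridge_propensity()], or
#'   any data frame with `pos_residue`, `neg_residue` and one or more value
#'   columns.
#' @param value_cols names of the propensity columns to aggregate
#'   (default `"total"`, or `c("intra","inter","total")` when present).
#' @param spec an [alloform()] spec (for row labels).
#' @return object of class `saltbridge_table`: list with `pairs` (input
#'   rows, ordered), `totals` (per positive residue, unrounded), `average_total`,
#'   and `display` (integer-rounded data frame in table layout).
#' @export
aggregate_table <- function(per_pair, value_cols = NULL,
                            spec = alloform("Ab42")) {
  if (is.null(value_cols)) {
    value_cols <- intersect(c("intra", "inter", "total"), names(per_pair))
    value_cols <- value_cols[vapply(value_cols,
                                    function(v) !all(is.na(per_pair[[v]])),
                                    logical(1))]
    if (!length(value_cols)) stop("no propensity value columns found")
  }
  pos <- spec$positive_residues
  neg <- spec$negative_residues
  for (p in pos) {
    have <- per_pair$neg_residue[per_pair$pos_residue == p]
    if (!setequal(have, neg) || length(have) != length(neg))
      stop("expected exactly the six negative partners for positive residue ",
           residue_label(spec, p))
  }
  ord <- order(match(per_pair$pos_residue, pos),
               match(per_pair$neg_residue, neg))
  per_pair <- per_pair[ord, , drop = FALSE]
  totals <- sapply(value_cols, function(v)
    sapply(pos, function(p) sum(per_pair[[v]][per_pair$pos_residue == p])))
  totals <- matrix(totals, nrow = length(pos),
                   dimnames = list(paste0("TOTAL ",
                                          sapply(pos, residue_label, spec = spec)),
                                   value_cols))
  avg <- colMeans(totals)
  disp_rows <- data.frame(row = per_pair$pair,
                          round_half_up(as.matrix(per_pair[, value_cols,
                                                           drop = FALSE])))
  disp <- rbind(disp_rows,
                data.frame(row = rownames(totals), round_half_up(totals)),
                data.frame(row = "Average TOTAL",
                           t(round_half_up(avg))))
  rownames(disp) <- NULL
  structure(list(pairs = per_pair, totals = totals, average_total = avg,
                 value_cols = value_cols, display = disp),
            class = "saltbridge_table")
}

#' @export
print.saltbridge_table <- function(x, ...) {
  cat("salt-bridge propensity table [%]\n")
  print(x$display, row.names = FALSE)
  invisible(x)
}

#' Write a salt-bridge table as TSV (pair rows, TOTAL rows, Average TOTAL)
#' @param x a `saltbridge_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_saltbridge_table <- function(x, path) {
  utils::write.table(x$display, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled reference per-pair salt-bridge propensities
#'
#' Loads the package's reference per-pair propensity values (percent) for
#' Abeta40/Abeta42 monomers and dimers with the SPCE and TIP3P water
#' models, shipped as plain-text TSVs. These serve as worked-example inputs
#' for [aggregate_table()].
#'
#' @param which `"monomer"` or `"dimer"`.
#' @return data frame; monomer columns are intrapeptide propensities per
#'   alloform/water model, dimer columns carry intra/inter/total blocks.
#' @export
reference_saltbridge_pairs <- function(which = c("monomer", "dimer")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("saltbridge_", which, "_reference.tsv"),
                      package = "abensemble", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
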