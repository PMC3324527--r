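# Independent oracles and small fixture builders used across the suite.
# Each oracle is a second, deliberately naive implementation kept separate
# from the package's code paths.

# --- quaternion-eigenvalue optimal-superposition RMSD ---------------------
# Independent of the package's SVD-based Kabsch solution: the optimal
# rotation's quality is the largest eigenvalue of the 4x4 key matrix built
# from the covariance of the centered coordinate sets.
quaternion_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  S <- t(ac) %*% bc
  key <- matrix(0, 4, 4)
  key[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  key[1, 2] <- key[2, 1] <- S[2, 3] - S[3, 2]
  key[1, 3] <- key[3, 1] <- S[3, 1] - S[1, 3]
  key[1, 4] <- key[4, 1] <- S[1, 2] - S[2, 1]
  key[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  key[2, 3] <- key[3, 2] <- S[1, 2] + S[2, 1]
  key[2, 4] <- key[4, 2] <- S[1, 3] + S[3, 1]
  key[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  key[3, 4] <- key[4, 3] <- S[2, 3] + S[3, 2]
  key[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lambda) / nrow(a)
  sqrt(max(0, msd))
}

# --- brute-force contact counting -----------------------------------------
brute_contact_number <- function(ca1, ca2, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(ca1))) for (j in seq_len(nrow(ca2))) {
    if (sqrt(sum((ca1[i, ] - ca2[j, ])^2)) < cutoff) n <- n + 1L
  }
  n
}

brute_contact_matrix <- function(ca1, ca2, cutoff, n_res) {
  m <- matrix(0, n_res, n_res)
  i1 <- as.integer(rownames(ca1)); i2 <- as.integer(rownames(ca2))
  for (i in seq_along(i1)) for (j in seq_along(i2)) {
    if (sqrt(sum((ca1[i, ] - ca2[j, ])^2)) < cutoff)
      m[i1[i], i2[j]] <- 1
  }
  m
}

# --- exhaustive salt-bridge scan ------------------------------------------
brute_salt_bridges <- function(c, cutoff, spec) {
  a <- c$atoms
  hits <- list()
  for (pp in unique(a$peptide_id)) for (np in unique(a$peptide_id)) {
    for (pr in spec$positive_residues) for (nr in spec$negative_residues) {
      ni <- which(a$peptide_id == pp & a$residue_index == pr &
                    a$element == "N" & a$atom_name != "N")
      oi <- which(a$peptide_id == np & a$residue_index == nr &
                    a$element == "O" & !(a$atom_name %in% c("O", "OXT")))
      found <- FALSE
      for (i in ni) for (j in oi) {
        if (sqrt(sum((c$xyz[i, ] - c$xyz[j, ])^2)) < cutoff) found <- TRUE
      }
      if (found)
        hits[[length(hits) + 1L]] <- c(pr, nr, pp, np)
    }
  }
  if (!length(hits)) return(matrix(integer(0), 0, 4))
  do.call(rbind, hits)
}

# --- dense numerical SASA of two overlapping spheres ----------------------
# Exact closed form for two spheres of radius R1, R2 (probe-expanded) at
# center distance d: exposed area of each sphere is its total area minus
# the spherical cap hidden inside the other sphere.
two_sphere_areas <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  cap_height <- function(R, r, d) R - (d^2 + R^2 - r^2) / (2 * d)
  h1 <- cap_height(R1, R2, d)
  h2 <- cap_height(R2, R1, d)
  c(4 * pi * R1^2 - 2 * pi * R1 * max(0, h1),
    4 * pi * R2^2 - 2 * pi * R2 * max(0, h2))
}

# --- fixture builders ------------------------------------------------------
# CA-only chain with optional per-residue side-chain N/O pseudo-atoms,
# assembled directly from coordinates (bypasses the generators).
make_ca_conformation <- function(ca_list, codes = NULL) {
  rows <- list(); coords <- list()
  for (p in seq_along(ca_list)) {
    ca <- ca_list[[p]]
    n <- nrow(ca)
    cd <- if (is.null(codes)) rep("A", n) else codes
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- abensemble:::.atom_block(p, i, cd[i],
                                                           "CA", "C")
      coords[[length(coords) + 1L]] <- ca[i, ]
    }
  }
  conformation(do.call(rbind, rows), do.call(rbind, coords),
               validate = FALSE)
}

# single-trajectory ensemble from a list of conformations (same topology)
make_ensemble <- function(frames, interval = 50) {
  arr <- array(0, dim = c(nrow(frames[[1]]$atoms), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]$xyz
  ensemble(frames[[1]]$atoms,
           list(list(times = interval * seq_along(frames), xyz = arr)),
           interval = interval)
}

# random rigid motion
random_rigid <- function() {
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = rnorm(3, sd = 20))
}

# united-atom heavy-atom counts per residue (backbone N,CA,C,O plus side
# chain), the standard composition table, frozen independently of the
# package's template library
heavy_atom_counts <- c(G = 4, A = 5, S = 6, C = 6, T = 7, V = 7, P = 7,
                       L = 8, I = 8, M = 8, N = 8, D = 8, K = 9, Q = 9,
                       E = 9, H = 10, F = 11, R = 11, Y = 12, W = 14)
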