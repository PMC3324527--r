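spec42 <- alloform("Ab42")

# helper: charged-pair pseudo-peptide with controllable N-O distances
charged_conformation <- function(seed = 1, n_pep = 1, spread = 8) {
  set.seed(seed)
  cfg <- generator_config(seed = seed, n_trajectories = 1,
                          frames_per_trajectory = 1,
                          target_contact_number = 10)
  e <- if (n_pep == 2) gen_dimer_ensemble(cfg, spec42)
       else gen_monomer_ensemble(cfg, spec42)
  get_frame(e, 1, 1)
}

test_that("salt-bridge detection uses side-chain N-O minimum distances", {
  c1 <- charged_conformation(seed = 51)
  a <- c1$atoms
  # place R5's side-chain N 3 A from D1's side-chain O
  ni <- which(a$residue_index == 5 & a$atom_name == "NH1")
  oi <- which(a$residue_index == 1 & a$atom_name == "OD1")
  c1$xyz[ni, ] <- c1$xyz[oi, ] + c(3, 0, 0)
  det <- detect_salt_bridges(c1, cutoff = 4.0, spec = spec42)
  expect_true(any(det$pos_residue == 5 & det$neg_residue == 1))
  # push everything apart: empty set
  c2 <- charged_conformation(seed = 52)
  a2 <- c2$atoms
  sc <- a2$atom_name %in% c("NH1", "NZ", "OD1", "OE1")
  c2$xyz[sc, ] <- c2$xyz[sc, ] + 500 * matrix(seq_len(sum(sc)), sum(sc), 3)
  expect_equal(nrow(detect_salt_bridges(c2, cutoff = 4.0, spec = spec42)), 0L)
})

test_that("detection equals the exhaustive N-O scan on random conformations", {
  for (seed in 53:57) {
    cc <- charged_conformation(seed = seed)
    # compress to make some bridges likely
    cc$xyz <- cc$xyz * 0.45
    det <- detect_salt_bridges(cc, cutoff = 4.0, spec = spec42)
    brute <- brute_salt_bridges(cc, 4.0, spec42)
    got <- if (nrow(det)) paste(det$pos_residue, det$neg_residue,
                                det$pos_peptide, det$neg_peptide)
           else character(0)
    want <- if (nrow(brute)) paste(brute[, 1], brute[, 2],
                                   brute[, 3], brute[, 4])
            else character(0)
    expect_setequal(got, want)
  }
})

test_that("detection is symmetric under peptide relabeling of a dimer", {
  cc <- charged_conformation(seed = 58, n_pep = 2)
  cc$xyz <- cc$xyz * 0.5
  det <- detect_salt_bridges(cc, cutoff = 6.0, spec = spec42)
  # swap peptide labels
  sw <- cc
  sw$atoms$peptide_id <- 3L - sw$atoms$peptide_id
  det2 <- detect_salt_bridges(sw, cutoff = 6.0, spec = spec42)
  key <- function(d, flip = FALSE) sort(paste(
    d$pos_residue, d$neg_residue,
    if (flip) 3L - d$pos_peptide else d$pos_peptide,
    if (flip) 3L - d$neg_peptide else d$neg_peptide))
  expect_equal(key(det2, flip = TRUE), key(det))
})

test_that("propensities are rigid-motion invariant and monomers report no interpeptide class", {
  sb <- data.frame(pos_residue = 16, neg_residue = 11,
                   occupancy = 0.5, dwell = 4)
  cfg <- generator_config(seed = 59, n_trajectories = 2,
                          frames_per_trajectory = 10,
                          saltbridge_spec = sb)
  e <- gen_saltbridge_telegraph(cfg, gen_monomer_ensemble(cfg, spec42))
  pp <- saltbridge_propensity(e, cutoff = 4.0, spec = spec42)
  expect_true(all(is.na(pp$inter)))      # structurally absent, not 0
  expect_true(all(pp$intra >= 0 & pp$intra <= 100))
  # rotate + translate every frame rigidly: identical propensities
  set.seed(60); rt <- random_rigid()
  e2 <- e
  for (ti in seq_along(e2$trajectories)) {
    for (f in seq_along(e2$trajectories[[ti]]$times)) {
      e2$trajectories[[ti]]$xyz[, , f] <-
        sweep(e2$trajectories[[ti]]$xyz[, , f] %*% t(rt$R), 2, rt$t, "+")
    }
  }
  pp2 <- saltbridge_propensity(e2, cutoff = 4.0, spec = spec42)
  expect_equal(pp2$intra, pp$intra, tolerance = 1e-12)
})

test_that("the propensity estimator is unbiased on telegraph data", {
  p <- 0.4
  ests <- vapply(1:20, function(s) {
    sb <- data.frame(pos_residue = 5, neg_residue = 1,
                     occupancy = p, dwell = 4)
    cfg <- generator_config(seed = 700 + s, n_trajectories = 3,
                            frames_per_trajectory = 40,
                            saltbridge_spec = sb)
    e <- gen_saltbridge_telegraph(cfg, gen_monomer_ensemble(cfg, spec42))
    pp <- saltbridge_propensity(e, cutoff = 4.0, spec = spec42)
    pp$intra[pp$pos_residue == 5 & pp$neg_residue == 1]
  }, numeric(1))
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 100 * p), 3 * se_mean)
})

test_that("table aggregation reproduces the reference monomer columns", {
  ref <- reference_saltbridge_pairs("monomer")
  # printed TOTAL and Average TOTAL rows per alloform x water model
  expected <- list(
    Ab40.SPCE  = list(tot = c(65, 21, 38), avg = 41),
    Ab40.TIP3P = list(tot = c(96, 23, 46), avg = 55),
    Ab42.SPCE  = list(tot = c(85, 26, 30), avg = 47),
    Ab42.TIP3P = list(tot = c(103, 34, 52), avg = 63))
  for (key in names(expected)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- ref[ref$alloform == parts[1] & ref$water == parts[2], ]
    tab <- aggregate_table(sub, value_cols = "intra",
                           spec = alloform(parts[1]))
    expect_equal(unname(tab$totals[, "intra"]), expected[[key]]$tot)
    expect_equal(unname(abensemble:::round_half_up(tab$average_total)),
                 expected[[key]]$avg)
  }
})

test_that("table aggregation reproduces the reference dimer blocks", {
  ref <- reference_saltbridge_pairs("dimer")
  expected <- list(
    Ab40.SPCE  = list(intra = c(62, 15, 33), inter = c(14, 19, 12),
                      total = c(76, 34, 45), avg = c(37, 15, 52)),
    Ab40.TIP3P = list(intra = c(70, 29, 41), inter = c(13, 7, 17),
                      total = c(83, 37, 59), avg = c(47, 12, 60)),
    Ab42.SPCE  = list(intra = c(77, 13, 18), inter = c(12, 10, 7),
                      total = c(89, 24, 26), avg = c(36, 10, 46)),
    Ab42.TIP3P = list(intra = c(90, 14, 28), inter = c(10, 15, 14),
                      total = c(101, 29, 43), avg = c(44, 13, 58)))
  for (key in names(expected)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- ref[ref$alloform == parts[1] & ref$water == parts[2], ]
    tab <- aggregate_table(sub, value_cols = c("intra", "inter", "total"),
                           spec = alloform(parts[1]))
    for (col in c("intra", "inter", "total"))
      expect_equal(unname(tab$totals[, col]), expected[[key]][[col]])
    expect_equal(unname(abensemble:::round_half_up(tab$average_total)),
                 expected[[key]]$avg)
  }
})

test_that("aggregates follow the pre-rounding conventions", {
  # TOTAL equals the exact column sum before rounding
  pp <- data.frame(pos_residue = rep(c(5, 16, 28), each = 6),
                   neg_residue = rep(c(1, 3, 7, 11, 22, 23), 3),
                   total = c(8.4, 17.3, 18.6, 11.2, 7.9, 1.6,
                             rep(1.5, 6), rep(0, 6)))
  pp$pair <- paste0("p", seq_len(nrow(pp)))
  tab <- aggregate_table(pp, value_cols = "total", spec = spec42)
  expect_equal(unname(tab$totals[, 1]),
               c(sum(pp$total[1:6]), 9, 0))
  expect_equal(unname(tab$average_total),
               mean(c(sum(pp$total[1:6]), 9, 0)))
  # all-zero input -> zero aggregates
  pp0 <- pp; pp0$total <- 0
  tab0 <- aggregate_table(pp0, value_cols = "total", spec = spec42)
  expect_true(all(tab0$totals == 0) && all(tab0$average_total == 0))
  # half-up display rounding
  expect_equal(abensemble:::round_half_up(c(0.5, 1.5, 41.33, 2.49)),
               c(1, 2, 41, 2))
  # six negative partners are mandatory
  expect_error(aggregate_table(pp[-1, ], value_cols = "total",
                               spec = spec42), "six")
})
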