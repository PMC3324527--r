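spec42 <- alloform("Ab42")

test_that("monomer generator builds exact-bond self-avoiding chains", {
  cfg <- generator_config(seed = 10, n_trajectories = 1,
                          frames_per_trajectory = 1)   # compactness = Inf
  e <- gen_monomer_ensemble(cfg, spec42)
  ca <- calpha_coords(get_frame(e, 1, 1))
  bonds <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(bonds - 3.8) < 1e-6))
  # non-adjacent Calpha pairs at least 4 A apart
  d2 <- abensemble:::.cross_dist2(ca, ca)
  offdiag <- abs(row(d2) - col(d2)) >= 2
  expect_true(all(d2[offdiag] >= 4.0^2 - 1e-9))
})

test_that("generators are deterministic under a fixed seed and decorrelate across seeds", {
  cfg <- generator_config(seed = 3, n_trajectories = 2,
                          frames_per_trajectory = 4)
  e1 <- gen_monomer_ensemble(cfg, spec42)
  e2 <- gen_monomer_ensemble(cfg, spec42)
  expect_identical(e1$trajectories, e2$trajectories)
  cfgB <- generator_config(seed = 104, n_trajectories = 2,
                           frames_per_trajectory = 4)
  e3 <- gen_monomer_ensemble(cfgB, spec42)
  # frame-wise decorrelation across seeds: the per-frame displacement
  # fields of two independent runs are uncorrelated (raw coordinates of
  # any two random walks correlate spuriously, so displacements are the
  # meaningful check)
  d1 <- as.vector(e1$trajectories[[1]]$xyz[, , 2] -
                    e1$trajectories[[1]]$xyz[, , 1])
  d3 <- as.vector(e3$trajectories[[1]]$xyz[, , 2] -
                    e3$trajectories[[1]]$xyz[, , 1])
  expect_lt(abs(cor(d1, d3)), 0.2)
  # trajectory subsets reproduce: trajectory 2 alone equals trajectory 2
  # of the two-trajectory run (per-trajectory derived seeds)
  cfg1 <- generator_config(seed = 3, n_trajectories = 1,
                           frames_per_trajectory = 4)
  expect_identical(gen_monomer_ensemble(cfg1, spec42)$trajectories[[1]],
                   e1$trajectories[[1]])
})

test_that("compactness rescaling recovers the target radius of gyration", {
  cfg <- generator_config(seed = 8, n_trajectories = 2,
                          frames_per_trajectory = 100, compactness = 9)
  e <- gen_monomer_ensemble(cfg, spec42)
  rg <- unlist(map_frames(e, radius_of_gyration))
  expect_lt(abs(mean(rg) - 9) / 9, 0.05)
  expect_error(gen_monomer_ensemble(
    generator_config(seed = 1, compactness = 1), spec42),
    "close-packing")
})

test_that("dimer generator hits the contact target and exposes N-termini", {
  cfg <- generator_config(seed = 6, n_trajectories = 2,
                          frames_per_trajectory = 8,
                          target_contact_number = 20)
  e <- gen_dimer_ensemble(cfg, spec42)
  cn <- unlist(map_frames(e, function(f) contact_number(f, 7.5)))
  expect_true(all(cn >= 18 & cn <= 22))
  n_exposed <- 0L; n_total <- 0L
  for (ti in 1:2) for (fi in 1:8) {
    f <- get_frame(e, ti, fi)
    cm <- center_of_mass(f)
    for (p in 1:2) {
      ca <- calpha_coords(f, p)
      d <- sqrt(rowSums(sweep(ca, 2, cm)^2))
      nr <- nrow(ca)
      n_total <- n_total + 1L
      if (mean(d[1:5]) > mean(d[(nr - 4):nr])) n_exposed <- n_exposed + 1L
    }
  }
  expect_gte(n_exposed / n_total, 0.95)
  # zero-contact target separates the chains beyond the cutoff
  cfg0 <- generator_config(seed = 6, n_trajectories = 1,
                           frames_per_trajectory = 2,
                           target_contact_number = 0)
  e0 <- gen_dimer_ensemble(cfg0, spec42)
  expect_equal(unlist(map_frames(e0, function(f) contact_number(f, 7.5))),
               c(0L, 0L))
})

test_that("telegraph dynamics give degenerate propensities at p = 0 and 1", {
  for (p in c(0, 1)) {
    sb <- data.frame(pos_residue = 5, neg_residue = 1,
                     occupancy = p, dwell = 5)
    cfg <- generator_config(seed = 12, n_trajectories = 2,
                            frames_per_trajectory = 30,
                            saltbridge_spec = sb)
    e <- gen_saltbridge_telegraph(cfg, gen_monomer_ensemble(cfg, spec42))
    pp <- saltbridge_propensity(e, cutoff = 4.0, spec = spec42)
    got <- pp$intra[pp$pos_residue == 5 & pp$neg_residue == 1]
    expect_equal(got, 100 * p)
  }
  expect_error(generator_config(saltbridge_spec = data.frame(
    pos_residue = 5, neg_residue = 1, occupancy = 1.2, dwell = 5)),
    "occupancy")
})

test_that("telegraph occupancy is recovered within sampling error", {
  sb <- data.frame(pos_residue = 5, neg_residue = 1,
                   occupancy = 0.65, dwell = 10)
  cfg <- generator_config(seed = 11, n_trajectories = 6,
                          frames_per_trajectory = 200,
                          saltbridge_spec = sb)
  e <- gen_saltbridge_telegraph(cfg, gen_monomer_ensemble(cfg, spec42))
  pp <- saltbridge_propensity(e, cutoff = 4.0, spec = spec42)
  row <- pp[pp$pos_residue == 5 & pp$neg_residue == 1, ]
  expect_lt(abs(row$intra - 65), 3 * row$intra_sem)
})

test_that("water shell realizes the requested density and excluded volume", {
  at <- abensemble:::.atom_block(1, 1, "A", "CA", "C")
  solute <- conformation(at, matrix(0, 1, 3), validate = FALSE)
  cfg <- generator_config(seed = 9, water_density = 0.0334, box_radius = 15)
  w <- gen_water_shell(cfg, solute)
  v_box <- 30^3
  v_excl <- 4 / 3 * pi * 2.6^3
  expected <- 0.0334 * (v_box - v_excl)
  expect_lt(abs(nrow(w) - expected), 3 * sqrt(expected))
  expect_true(all(sqrt(rowSums(w^2)) >= 2.6))
  # zero density -> empty set
  cfg0 <- generator_config(seed = 9, water_density = 0, box_radius = 15)
  expect_equal(nrow(gen_water_shell(cfg0, solute)), 0L)
  # absurd density refuses to run
  cfgX <- generator_config(seed = 9, water_density = 1e4, box_radius = 50)
  expect_error(gen_water_shell(cfgX, solute), "density")
})

test_that("four-bead generator emits the right bead inventory", {
  cfg <- generator_config(seed = 4)
  cg <- gen_cg_conformer(cfg, spec42)
  n_gly <- sum(strsplit(spec42$sequence, "")[[1]] == "G")
  expect_equal(nrow(cg$atoms), 3L * 42L + (42L - n_gly))
  expect_equal(sum(cg$atoms$atom_name == "CA"), 42L)
  # Gly-only chain has no side-chain beads
  cg_gly <- gen_cg_conformer(cfg, sequence = strrep("G", 12))
  expect_equal(nrow(cg_gly$atoms), 36L)
  expect_false(any(cg_gly$atoms$atom_name == "CB"))
  # reproducible under the seed
  expect_identical(gen_cg_conformer(cfg, spec42)$xyz, cg$xyz)
})

test_that("generated ensembles satisfy the conformation invariants", {
  cfg <- generator_config(seed = 13, n_trajectories = 1,
                          frames_per_trajectory = 3,
                          target_contact_number = 15)
  for (e in list(gen_monomer_ensemble(cfg, spec42),
                 gen_dimer_ensemble(cfg, spec42))) {
    for (fi in 1:3)
      expect_true(validate_conformation(get_frame(e, 1, fi)))
  }
})
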