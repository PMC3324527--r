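spec40 <- alloform("Ab40")

test_that("center of mass and radius of gyration match direct sums", {
  at1 <- abensemble:::.atom_block(1, 1, "A", "CA", "C")
  single <- conformation(at1, matrix(c(1, 2, 3), 1), validate = FALSE)
  expect_equal(center_of_mass(single), c(1, 2, 3))
  expect_equal(radius_of_gyration(single), 0)

  two <- make_ca_conformation(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(center_of_mass(two), c(1, 0, 0))
  rg2 <- make_ca_conformation(list(rbind(c(-1, 0, 0), c(1, 0, 0))))
  expect_equal(radius_of_gyration(rg2), 1)

  set.seed(31)
  at <- do.call(rbind, lapply(1:20, function(i) rbind(
    abensemble:::.atom_block(1, i, "A", "CA", "C"),
    abensemble:::.atom_block(1, i, "A", "NZ", "N"),
    abensemble:::.atom_block(1, i, "A", "OD1", "O"),
    abensemble:::.atom_block(1, i, "A", "SD", "S"),
    abensemble:::.atom_block(1, i, "A", "CB", "C"))))
  xyz <- matrix(rnorm(nrow(at) * 3, sd = 10), ncol = 3)
  c100 <- conformation(at, xyz, validate = FALSE)
  m <- at$mass
  cm_brute <- c(sum(m * xyz[, 1]), sum(m * xyz[, 2]), sum(m * xyz[, 3])) / sum(m)
  expect_lt(max(abs(center_of_mass(c100) - cm_brute)), 1e-10)
  rg_brute <- sqrt(sum(m * rowSums(sweep(xyz, 2, cm_brute)^2)) / sum(m))
  expect_lt(abs(radius_of_gyration(c100) - rg_brute), 1e-10)
  expect_error(center_of_mass(c100, selection = rep(FALSE, nrow(at))),
               "empty")
})

test_that("NT-CM distance acts as an effective radius", {
  # 3-4-5 triangle: CM at origin, N-terminal Calpha at (3,4,0)
  ca <- rbind(c(3, 4, 0), c(-3, -4, 0))
  expect_equal(nt_cm_distance(make_ca_conformation(list(ca)))[1], 5)
  # mirror-symmetric dimer gives two equal values
  set.seed(7)
  chain <- matrix(rnorm(15, sd = 5), 5)
  dimer <- make_ca_conformation(list(chain, -chain))
  v <- nt_cm_distance(dimer)
  expect_equal(v[1], v[2])
})

test_that("residue CM-distance profile equals the per-frame brute force", {
  ca3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  lin <- make_ca_conformation(list(ca3))
  prof1 <- residue_cm_distances(make_ensemble(list(lin)))
  expect_equal(prof1$values, c(1, 0, 1))
  # identical coordinates -> all zeros
  same <- make_ca_conformation(list(matrix(5, 4, 3)))
  expect_equal(residue_cm_distances(make_ensemble(list(same)))$values,
               rep(0, 4))
  # synthetic dimer ensemble vs loop oracle
  cfg <- generator_config(seed = 14, n_trajectories = 2,
                          frames_per_trajectory = 4,
                          target_contact_number = 12)
  e <- gen_dimer_ensemble(cfg, spec40)
  prof <- residue_cm_distances(e)
  n_res <- 40
  per_traj <- sapply(1:2, function(ti) {
    acc <- matrix(0, n_res, 0)
    for (fi in 1:4) {
      f <- get_frame(e, ti, fi)
      cm <- center_of_mass(f)
      per_res <- sapply(1:n_res, function(r) {
        sel <- f$atoms$atom_name == "CA" & f$atoms$residue_index == r
        mean(sqrt(rowSums(sweep(f$xyz[sel, , drop = FALSE], 2, cm)^2)))
      })
      acc <- cbind(acc, per_res)
    }
    rowMeans(acc)
  })
  expect_lt(max(abs(prof$values - rowMeans(per_traj))), 1e-10)
})

test_that("contact number matches brute force and is monotone in the cutoff", {
  far <- make_ca_conformation(list(matrix(0, 3, 3) + diag(3) * 4,
                                   matrix(100, 3, 3) + diag(3) * 4))
  expect_equal(contact_number(far, 7.5), 0L)
  # complete bipartite: all cross distances 5 A below a 7.5 A cutoff
  c1 <- rbind(c(0, 0, 0), c(0, 4, 0), c(0, 8, 0))
  c2 <- sweep(c1, 2, c(5, 0, 0), "+")
  allpairs <- make_ca_conformation(list(c1, c2))
  expect_equal(contact_number(allpairs, 7.5),
               brute_contact_number(c1, c2, 7.5))
  set.seed(41)
  for (rep in 1:10) {
    a <- matrix(rnorm(60, sd = 6), 20)
    b <- matrix(rnorm(60, sd = 6), 20)
    d <- make_ca_conformation(list(a, b))
    expect_equal(contact_number(d, 7.5), brute_contact_number(a, b, 7.5))
    expect_gte(contact_number(d, 9.0), contact_number(d, 7.5))
  }
  mono <- make_ca_conformation(list(matrix(rnorm(30), 10)))
  expect_error(contact_number(mono), "dimer")
})

test_that("distances, Rg and contacts are invariant under rigid motion", {
  set.seed(42)
  a <- matrix(rnorm(60, sd = 6), 20)
  b <- matrix(rnorm(60, sd = 6), 20)
  d <- make_ca_conformation(list(a, b))
  for (rep in 1:5) {
    rt <- random_rigid()
    d2 <- transform_conformation(d, rt$R, rt$t)
    expect_equal(contact_number(d2, 7.5), contact_number(d, 7.5))
    expect_lt(abs(radius_of_gyration(d2) - radius_of_gyration(d)), 1e-8)
    expect_lt(max(abs(nt_cm_distance(d2) - nt_cm_distance(d))), 1e-8)
  }
})

test_that("contact maps average frame indicators and symmetrize correctly", {
  # frozen ensemble: one repeated frame -> 0/1 entries, SEM 0
  set.seed(43)
  a <- matrix(rnorm(24, sd = 5), 8)
  b <- matrix(rnorm(24, sd = 5), 8)
  frame <- make_ca_conformation(list(a, b))
  e2 <- ensemble(frame$atoms,
                 list(list(times = c(50, 100),
                           xyz = array(rep(frame$xyz, 2), c(16, 3, 2))),
                      list(times = c(50, 100),
                           xyz = array(rep(frame$xyz, 2), c(16, 3, 2)))),
                 interval = 50)
  m <- contact_map(e2, cutoff = 7.5, kind = "inter")
  expect_true(all(m$matrix %in% c(0, 0.5, 1)))  # symmetrized indicator
  expect_true(all(m$sem == 0))
  # intra map is exactly symmetric; diagonal band is 1 for connected chains
  cfg <- generator_config(seed = 15, n_trajectories = 2,
                          frames_per_trajectory = 5)
  em <- gen_monomer_ensemble(cfg, spec40)
  mi <- contact_map(em, cutoff = 7.5, kind = "intra")
  expect_identical(mi$matrix, t(mi$matrix))
  expect_true(all(abs(diag(mi$matrix) - 1) < 1e-12))
  band <- cbind(1:39, 2:40)
  expect_true(all(mi$matrix[band] == 1))  # cutoff exceeds the bond length
  expect_true(all(mi$matrix >= 0 & mi$matrix <= 1))
  # brute-force frame-by-frame average for the inter map
  cfgd <- generator_config(seed = 16, n_trajectories = 1,
                           frames_per_trajectory = 10,
                           target_contact_number = 15)
  ed <- gen_dimer_ensemble(cfgd, spec40)
  mi2 <- contact_map(ed, cutoff = 7.5, kind = "inter")
  acc <- matrix(0, 40, 40)
  for (fi in 1:10) {
    f <- get_frame(ed, 1, fi)
    ca1 <- calpha_coords(f, 1); ca2 <- calpha_coords(f, 2)
    ind <- brute_contact_matrix(ca1, ca2, 7.5, 40)
    acc <- acc + (ind + t(ind)) / 2
  }
  expect_lt(max(abs(mi2$matrix - acc / 10)), 1e-12)
})

test_that("contact numbers are robust across cutoffs with an empty gap", {
  # constructed dimers with no cross-peptide pair between 7.5 and 8.0 A:
  # both cutoffs must then count identically
  set.seed(44)
  for (rep in 1:20) {
    a <- matrix(rnorm(45, sd = 6), 15)
    b <- matrix(rnorm(45, sd = 6), 15)
    d2 <- abensemble:::.cross_dist2(a, b)
    gap <- sqrt(d2) >= 7.5 & sqrt(d2) < 8.0
    if (any(gap)) next   # only gap-free geometries exercise the property
    d <- make_ca_conformation(list(a, b))
    expect_equal(contact_number(d, 7.5), contact_number(d, 8.0))
  }
  # and an explicit gap-free construction
  c1 <- rbind(c(0, 0, 0), c(0, 5, 0))
  c2 <- rbind(c(7.0, 0, 0), c(9.0, 5, 0))
  d <- make_ca_conformation(list(c1, c2))
  expect_equal(contact_number(d, 7.5), contact_number(d, 8.0))
})
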