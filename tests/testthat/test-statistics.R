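spec40 <- alloform("Ab40")

test_that("trajectory-level mean and SEM follow the closed form", {
  expect_equal(mean_sem(list(rep(3, 5), rep(3, 2))),
               list(mean = 3, sem = 0, n_trajectories = 2L))
  ms <- mean_sem(list(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3))
  # single trajectory: mean defined, SEM unavailable
  ms1 <- mean_sem(list(c(1, 2, 3)))
  expect_equal(ms1$mean, 2)
  expect_true(is.na(ms1$sem))
  # SEM is zero iff all trajectory means coincide
  expect_equal(mean_sem(list(c(0, 2), c(1, 1)))$sem, 0)
  expect_gt(mean_sem(list(c(0, 2), c(1, 2)))$sem, 0)
})

test_that("RMSD series are zero for rigid motion and bounded by the unaligned RMSD", {
  cfg <- generator_config(seed = 81, n_trajectories = 1,
                          frames_per_trajectory = 1)
  f0 <- get_frame(gen_monomer_ensemble(cfg, spec40), 1, 1)
  # rigid-motion trajectory: all zeros
  frames <- lapply(1:6, function(i) {
    set.seed(100 + i); rt <- random_rigid()
    transform_conformation(f0, rt$R, rt$t)
  })
  e <- make_ensemble(c(list(f0), frames))
  expect_true(all(rmsd_series(e, 1) < 1e-10))
  # diffusing trajectory: aligned RMSD never exceeds the unaligned value
  set.seed(82)
  drift <- list(f0)
  cur <- f0
  for (i in 1:8) {
    cur$xyz <- cur$xyz + matrix(rnorm(length(cur$xyz), sd = 0.6),
                                ncol = 3)
    drift[[i + 1]] <- cur
  }
  ed <- make_ensemble(drift)
  aligned <- rmsd_series(ed, 1)
  ca <- ed$topology$atom_name == "CA"
  unaligned <- vapply(seq_along(drift), function(i)
    sqrt(mean(rowSums((drift[[i]]$xyz[ca, ] - f0$xyz[ca, ])^2))) / 10,
    numeric(1))
  expect_true(all(aligned <= unaligned + 1e-12))
  expect_equal(aligned[1], 0)
})

test_that("extreme-RMSD trajectory selection returns the known extremes", {
  cfg <- generator_config(seed = 83, n_trajectories = 1,
                          frames_per_trajectory = 1)
  f0 <- get_frame(gen_monomer_ensemble(cfg, spec40), 1, 1)
  # per-trajectory deformation amplitude increases with the index
  set.seed(84)
  mk_traj <- function(amp) {
    frames <- lapply(1:4, function(i) {
      f <- f0
      f$xyz <- f$xyz + matrix(rnorm(length(f$xyz), sd = amp), ncol = 3)
      f
    })
    arr <- array(0, c(nrow(f0$atoms), 3, 5))
    arr[, , 1] <- f0$xyz
    for (i in 1:4) arr[, , i + 1] <- frames[[i]]$xyz
    list(times = 50 * (1:5), xyz = arr)
  }
  e <- ensemble(f0$atoms, lapply(c(0.05, 0.4, 1.2, 2.5), mk_traj),
                interval = 50)
  expect_equal(sort(select_extreme_trajectories(e, 2)), c(1L, 4L))
  expect_equal(select_extreme_trajectories(e, 1), 4L)
  expect_setequal(select_extreme_trajectories(e, 4), 1:4)
  expect_error(select_extreme_trajectories(e, 9), "exceeds")
})

test_that("convergence diagnostics separate stationary from drifting ensembles", {
  cfg <- generator_config(seed = 85, n_trajectories = 3,
                          frames_per_trajectory = 30, compactness = 10)
  e <- gen_monomer_ensemble(cfg, spec40)   # iid frames about one base
  wins <- list(c(0, 500), c(500, 1000), c(1000, 1500))
  rep1 <- convergence_check(e, mode = "time_windows", levels = wins,
                            tolerance = 1.0)
  expect_true(rep1$converged)
  expect_equal(length(rep1$max_abs_delta), 2L)
  # drifting ensemble: mean shifts 5 A between windows
  ed <- e
  for (ti in seq_along(ed$trajectories)) {
    tt <- ed$trajectories[[ti]]$times
    for (f in seq_along(tt)) {
      shift <- 5 * floor((tt[f] - 1) / 500)
      ca1 <- which(ed$topology$residue_index <= 5)
      ed$trajectories[[ti]]$xyz[ca1, 1, f] <-
        ed$trajectories[[ti]]$xyz[ca1, 1, f] + shift
    }
  }
  rep2 <- convergence_check(ed, mode = "time_windows", levels = wins,
                            tolerance = 1.0)
  expect_false(rep2$converged)
  # monotone in tolerance: converged at tau implies converged at tau' > tau
  last <- rep2$max_abs_delta[length(rep2$max_abs_delta)]
  rep3 <- convergence_check(ed, mode = "time_windows", levels = wins,
                            tolerance = last * 1.01)
  expect_true(rep3$converged)
  # trajectory-count mode and the single-level degenerate case
  rep4 <- convergence_check(e, mode = "trajectory_counts", levels = c(1, 2, 3),
                            tolerance = 2.0)
  expect_equal(length(rep4$curves), 3L)
  rep5 <- convergence_check(e, mode = "trajectory_counts", levels = 2)
  expect_true(is.na(rep5$converged))
})

test_that("secondary-structure propensities partition to 100 percent", {
  # all-turn labels
  m <- matrix("T", nrow = 10, ncol = 6)
  ssp <- ss_propensity(m)
  expect_equal(ssp$per_residue$turn$values, rep(100, 6))
  expect_equal(ssp$per_residue$coil$values, rep(0, 6))
  # 50/50 turn/coil alternating by frame
  m2 <- matrix(rep(c("T", "C"), each = 6, times = 10), ncol = 6,
               byrow = TRUE)
  ssp2 <- ss_propensity(list(m2, m2))
  expect_equal(ssp2$per_residue$turn$values, rep(50, 6))
  expect_true(all(ssp2$per_residue$turn$sem == 0))
  # class percentages sum to 100 exactly at every residue
  set.seed(86)
  m3 <- matrix(sample(c("T", "E", "H", "C"), 200, replace = TRUE),
               ncol = 8)
  ssp3 <- ss_propensity(m3)
  sums <- Reduce(`+`, lapply(ssp3$per_residue, `[[`, "values"))
  expect_equal(sums, rep(100, 8), tolerance = 1e-9)
  expect_error(ss_propensity(matrix("X", 2, 2)), "unknown")
})

test_that("label streams parse one frame per line", {
  tmp <- tempfile()
  writeLines(c("TTECH", "C C C C C", "HHHHH"), tmp)
  m <- read_ss_labels(tmp)
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(m[1, ], c("T", "T", "E", "C", "H"))
  writeLines(c("TTT", "TT"), tmp)
  expect_error(read_ss_labels(tmp), "inconsistent")
})
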