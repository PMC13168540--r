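test_that("membrane composition follows the configured ratios exactly", {
  cfg <- membrane_config(seed = 1, n_lipids_per_leaflet = 200L,
                         sterol_fraction = 0.1, box_xy = 12, n_frames = 2L,
                         n_saponins = 5L, n_waters = 100L)
  sys <- gen_membrane_system(cfg)
  at <- sys$trajectory$atoms
  expect_equal(sum(at$resname == "DOPC" & at$name == "P"), 2L * 180L)
  expect_equal(sum(at$resname == "CHL" & at$name == "O3"), 2L * 20L)
  expect_equal(sum(at$resname == "SAP"), 3L * 5L)
  expect_equal(sum(at$resname == "SOL"), 100L)
  expect_equal(n_atoms(sys$trajectory),
               2L * 200L * 3L + 5L * 3L + 100L)
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- membrane_config(seed = 42, n_frames = 3L)
  a <- gen_membrane_system(cfg)
  b <- gen_membrane_system(cfg)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ground_truth$schedule, b$ground_truth$schedule)

  t1 <- gen_leakage_experiment(c(-1.5, 0, 100, 20), c(0, 5, 10, 20, 50, 100),
                               seed = 9)
  t2 <- gen_leakage_experiment(c(-1.5, 0, 100, 20), c(0, 5, 10, 20, 50, 100),
                               seed = 9)
  expect_identical(t1, t2)

  v1 <- gen_viability_experiment(c(A = 0.3, B = 0.7), seed = 9)
  v2 <- gen_viability_experiment(c(A = 0.3, B = 0.7), seed = 9)
  expect_identical(v1, v2)
})

test_that("always-bound saponins sit at the bound depth without jitter", {
  cfg <- membrane_config(seed = 3, p_bound = 1, jitter_sd = 0,
                         n_frames = 5L, n_saponins = 4L)
  sys <- gen_membrane_system(cfg)
  tr <- sys$trajectory
  agl <- which(tr$atoms$resname == "SAP" & tr$atoms$name == "AGL")
  plane_u <- cfg$box_z / 2 + cfg$leaflet_z
  expect_true(all(abs(tr$coords[agl, 3, ] - (plane_u - 0.3)) < 1e-12))
  expect_true(all(sys$ground_truth$schedule))
})

test_that("schedule dimensions and realized fractions are consistent", {
  cfg <- membrane_config(seed = 8, p_bound = 0.6, n_frames = 40L,
                         n_saponins = 10L)
  sys <- gen_membrane_system(cfg)
  sch <- sys$ground_truth$schedule
  expect_equal(dim(sch), c(10L, 40L))
  expect_equal(sys$ground_truth$bound_fraction_per_molecule, rowMeans(sch))
})

test_that("oversubscribed boxes raise a sizing error", {
  expect_error(gen_membrane_system(
    membrane_config(seed = 1, n_lipids_per_leaflet = 500L, box_xy = 5)),
    "box too small")
})

test_that("point patterns: CSR bounds, Thomas clustering, unknown mode", {
  p <- gen_point_pattern("poisson", 2L, 10, seed = 4)
  expect_equal(dim(p), c(2L, 2L))
  expect_true(all(p >= 0 & p < 10))
  expect_error(gen_point_pattern("grid", 10L, 10), "unknown point-pattern")

  # Thomas offspring are closer together than CSR points at equal density
  mean_nn <- function(xy, box) {
    dx <- abs(outer(xy[, 1], xy[, 1], "-")); dx <- pmin(dx, box - dx)
    dy <- abs(outer(xy[, 2], xy[, 2], "-")); dy <- pmin(dy, box - dy)
    d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn <- vapply(1:100, function(s) {
    c(pois = mean_nn(gen_point_pattern("poisson", 100L, 10, seed = s), 10),
      thom = mean_nn(gen_point_pattern("thomas", 100L, 10,
                                       list(parent_intensity = 0.1,
                                            cluster_sd = 0.3),
                                       seed = s), 10))
  }, numeric(2))
  expect_lt(mean(nn["thom", ]), mean(nn["pois", ]))
  expect_gt(mean(nn["pois", ] - nn["thom", ]), 0)
  expect_true(all(nn["thom", ] < nn["pois", ]))
})

test_that("noise-free leakage tables invert exactly through the release formula", {
  conc <- c(0, 2, 5, 10, 20, 50, 100)
  tbl <- gen_leakage_experiment(c(-1.5, 0, 100, 20), conc, noise_sd = 0,
                                n_reps = 2L, seed = 6)
  rel <- as.numeric(percent_release(tbl))
  expect_lt(max(abs(rel - fourpl(tbl$concentration_uM, -1.5, 0, 100, 20))),
            1e-10)
  # release at the EC50 is the curve midpoint
  at_e <- gen_leakage_experiment(c(-2, 0, 100, 20), c(0, 1, 5, 20, 80, 100),
                                 noise_sd = 0, n_reps = 1L, seed = 6)
  rel_e <- as.numeric(percent_release(at_e))[at_e$concentration_uM == 20]
  expect_equal(rel_e, 50)
  # fixed I2 per replicate
  expect_equal(length(unique(tbl$I2)), 2L)
  expect_true(all(tbl$I1 > 0))
})

test_that("viability counts are binomial with the requested probabilities", {
  v0 <- gen_viability_experiment(c(none = 0), n_cells = 1000L, seed = 2)
  expect_true(all(v0$pi_positive == 0L))

  v <- gen_viability_experiment(c(hi = 0.9), n_cells = 10000L, n_reps = 5L,
                                seed = 3)
  frac <- v$pi_positive / v$total_cells
  expect_true(all(abs(frac - 0.9) < 3 * sqrt(0.9 * 0.1 / 10000)))
})
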