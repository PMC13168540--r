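test_that("binding classification recovers noise-free schedules exactly", {
  for (p in c(0.2, 0.5, 0.8)) {
    cfg <- membrane_config(seed = round(100 * p), p_bound = p, jitter_sd = 0,
                           n_saponins = 10L, n_frames = 40L)
    sys <- gen_membrane_system(cfg)
    phos <- select_atoms(sys$trajectory, "resname DOPC and name P")
    bt <- classify_binding(sys$trajectory, phosphate_selection = phos)
    expect_identical(bt$bound_matrix, sys$ground_truth$schedule)
    # population fraction equals the schedule-derived fraction
    sch <- sys$ground_truth$schedule[, bt$eval_frames, drop = FALSE]
    expect_equal(bt$population_fraction, mean(rowMeans(sch) >= 0.8))
  }
})

test_that("binding summary is robust to realistic positional jitter", {
  off <- vapply(1:5, function(s) {
    cfg <- membrane_config(seed = s, p_bound = 0.5, jitter_sd = 0.05,
                           n_saponins = 10L, n_frames = 40L)
    sys <- gen_membrane_system(cfg)
    phos <- select_atoms(sys$trajectory, "resname DOPC and name P")
    bt <- classify_binding(sys$trajectory, phosphate_selection = phos)
    sch <- sys$ground_truth$schedule[, bt$eval_frames, drop = FALSE]
    abs(sum(bt$summary$stably_inserted) - sum(rowMeans(sch) >= 0.8))
  }, numeric(1))
  expect_true(all(off <= 1))
})

test_that("molecules held far above the bilayer are never bound", {
  cfg <- membrane_config(seed = 4, p_bound = 0, jitter_sd = 0,
                         n_saponins = 3L, n_frames = 10L)
  sys <- gen_membrane_system(cfg)   # unbound depth is +1.5 nm
  phos <- select_atoms(sys$trajectory, "resname DOPC and name P")
  bt <- classify_binding(sys$trajectory, phosphate_selection = phos)
  expect_true(all(bt$summary$bound_fraction == 0))
  expect_equal(bt$population_fraction, 0)
})

test_that("classification demands aglycone atoms", {
  cfg <- membrane_config(seed = 4, n_saponins = 2L, n_frames = 2L)
  sys <- gen_membrane_system(cfg)
  phos <- select_atoms(sys$trajectory, "resname DOPC and name P")
  expect_error(classify_binding(sys$trajectory, phosphate_selection = phos,
                                aglycone_name = "NOPE"),
               "without aglycone atoms")
})

test_that("aglycone-sugar angles match constructed geometries", {
  fr <- function(xyz) list(xyz = xyz, box = c(10, 10, 10))
  expect_equal(aglycone_sugar_angle(fr(rbind(c(-1, 0, 0), c(0, 0, 0),
                                             c(1, 0, 0))), 2, 1, 3), 180)
  expect_equal(aglycone_sugar_angle(fr(rbind(c(-1, 0, 0), c(0, 0, 0),
                                             c(0, 1, 0))), 2, 1, 3), 90)
  expect_error(aglycone_sugar_angle(fr(rbind(c(0, 0, 0), c(0, 0, 0),
                                             c(1, 0, 0))), 2, 1, 3),
               "degenerate")

  sys <- gen_membrane_system(membrane_config(seed = 6, jitter_sd = 0,
                                             saponin_angle = 120,
                                             n_saponins = 1L, n_frames = 1L))
  tr <- sys$trajectory
  sap <- which(tr$atoms$resname == "SAP")
  ang <- aglycone_sugar_angle(traj_frame(tr, 1), sap[2], sap[1], sap[3])
  expect_equal(ang, 120, tolerance = 1e-9)
})

test_that("angles are invariant under rigid rotation and translation", {
  set.seed(31)
  xyz <- matrix(rnorm(9), 3, 3)
  fr <- list(xyz = xyz, box = c(10, 10, 10))
  a0 <- aglycone_sugar_angle(fr, 2, 1, 3)
  # random rotation via QR of a Gaussian matrix
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  fr2 <- list(xyz = xyz %*% Q + matrix(rep(c(3, -2, 7), each = 3), 3, 3),
              box = c(10, 10, 10))
  expect_lt(abs(aglycone_sugar_angle(fr2, 2, 1, 3) - a0), 1e-9)
})

test_that("SASA matches the analytic sphere and buries enclosed atoms", {
  s <- sasa(matrix(0, 1, 3), radii = 1.9)
  expect_lt(abs(s$total / (4 * pi * 3.3^2) - 1), 0.005)
  buried <- sasa(rbind(c(0, 0, 0), c(0, 0, 0.1)), radii = c(0.5, 3))
  expect_equal(buried$per_atom[1], 0)
})

test_that("SASA agrees with a refined-sampling oracle on random clusters", {
  set.seed(13)
  for (rep in 1:3) {
    xyz <- matrix(rnorm(30, sd = 2), 10, 3)
    r <- runif(10, 1.2, 2.0)
    lo <- sasa(xyz, r, n_sphere_points = 960L)
    hi <- sasa(xyz, r, n_sphere_points = 10000L)
    expect_lt(abs(lo$total / hi$total - 1), 0.02)
  }
})

test_that("SASA is monotone under addition of atoms", {
  set.seed(17)
  xyz <- matrix(rnorm(15, sd = 1.5), 5, 3)
  r <- rep(1.6, 5)
  base <- sasa(xyz, r)
  # far-away, non-overlapping atom strictly increases the total
  grown <- sasa(rbind(xyz, c(50, 0, 0)), c(r, 1.6))
  expect_gt(grown$total, base$total)
  expect_equal(grown$per_atom[1:5], base$per_atom)
  # fully-buried atom leaves the others' areas unchanged
  host <- rbind(c(0, 0, 0), c(20, 0, 0))
  with_buried <- sasa(rbind(host, c(0, 0, 0.2)), c(4, 1.5, 0.4))
  without <- sasa(host, c(4, 1.5))
  expect_equal(with_buried$per_atom[1:2], without$per_atom)
  expect_equal(with_buried$per_atom[3], 0)
})

test_that("hydrogen-bond counting honors geometric criteria", {
  # donor O at origin with H toward the acceptor
  fr <- function(ax, hy = 0) list(
    xyz = rbind(c(0, 0, 0), c(0.095, hy, 0), c(ax, 0, 0)),
    box = c(10, 10, 10))
  expect_equal(as.integer(count_hbonds(fr(0.28), 1, 3,
                                       hydrogens = list(2))), 1L)
  expect_equal(as.integer(count_hbonds(fr(0.40), 1, 3,
                                       hydrogens = list(2))), 0L)
  # bent D-H...A near 120 degrees fails the default angle cut
  bent <- list(xyz = rbind(c(0, 0, 0), c(0.08, 0.05, 0), c(0.28, 0, 0)),
               box = c(10, 10, 10))
  ang <- {
    hd <- bent$xyz[1, ] - bent$xyz[2, ]; ha <- bent$xyz[3, ] - bent$xyz[2, ]
    acos(sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))) * 180 / pi
  }
  expect_lt(ang, 150)
  expect_equal(as.integer(count_hbonds(bent, 1, 3, hydrogens = list(2))), 0L)
})

test_that("fallback counting is symmetric and warns without partners", {
  fr <- list(xyz = rbind(c(0, 0, 0), c(0.3, 0, 0), c(5, 5, 5)),
             box = c(10, 10, 10))
  a <- count_hbonds(fr, 1, 2:3)
  b <- count_hbonds(fr, 2:3, 1)
  expect_equal(as.integer(a), as.integer(b))
  expect_equal(attr(a, "mode"), "distance-only")
  expect_warning(z <- count_hbonds(fr, integer(0), 1), "no donors")
  expect_equal(as.integer(z), 0L)
})

test_that("solvation energy reduces to the pair-energy landmarks", {
  at <- data.frame(resid = 1:2, resname = c("SAP", "SOL"),
                   name = c("AGL", "OW"))
  tr <- trajectory(at, array(c(0, 0.3 * 2^(1 / 6), 0, 0, 0, 0), c(2, 3, 1)),
                   c(50, 50, 50))
  ff0 <- ff_params(data.frame(type = c("AGL", "OW"), sigma = 0.3,
                              epsilon = 0, charge = 0))
  expect_equal(solvation_energy(tr, 1, 2, ff0)$mean, 0)
  ff <- ff_params(data.frame(type = c("AGL", "OW"), sigma = 0.3,
                             epsilon = 0.65, charge = 0))
  expect_equal(solvation_energy(tr, 1, 2, ff)$mean, -0.65, tolerance = 1e-12)
})
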