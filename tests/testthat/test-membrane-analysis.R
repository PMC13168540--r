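test_that("leaflet assignment splits phosphates about the midplane", {
  xyz <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, -1), c(1, 1, -1))
  fr <- traj_frame(coords_trajectory(xyz, names = rep("P", 4)))
  la <- assign_leaflets(fr, 1:4)
  expect_equal(la$midplane_z, 0)
  expect_equal(la$labels, c("upper", "upper", "lower", "lower"))

  sys <- gen_membrane_system(membrane_config(seed = 5, n_frames = 1L))
  tr <- sys$trajectory
  phos <- select_atoms(tr, "resname DOPC and name P")
  la2 <- assign_leaflets(traj_frame(tr, 1), phos)
  expect_equal(sum(la2$labels == "upper"), sum(la2$labels == "lower"))

  flat <- traj_frame(coords_trajectory(rbind(c(0, 0, 1), c(1, 1, 1))))
  expect_error(assign_leaflets(flat, 1:2), "degenerate")
})

test_that("two isolated atoms give a single RDF bin at their separation", {
  xyz <- rbind(c(1, 1, 5), c(2, 1, 5))
  tr <- coords_trajectory(xyz, box = c(10, 10, 10), names = c("O3", "O3"))
  rdf <- lateral_rdf(tr, 1:2, leaflet = "upper", bin_width = 0.05, r_max = 4)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1L)
  expect_true(rdf$bin_centers[nz] > 0.95 && rdf$bin_centers[nz] < 1.05)
})

test_that("hexagonal lattice RDF peaks in the bin containing the spacing", {
  a <- 1
  nx <- 6L; ny <- 6L
  pts <- do.call(rbind, lapply(0:(ny - 1), function(row)
    cbind((0:(nx - 1)) * a + (row %% 2) * a / 2, row * a * sqrt(3) / 2)))
  box <- c(nx * a, ny * a * sqrt(3) / 2, 10)
  tr <- coords_trajectory(cbind(pts, 5), box = box,
                          names = rep("O3", nrow(pts)))
  rdf <- lateral_rdf(tr, seq_len(nrow(pts)), leaflet = "upper",
                     bin_width = 0.05, r_max = 2.5)
  # lattice distances of exactly a may straddle a bin edge in floating point
  first_nz <- which(rdf$g > 0)[1]
  expect_lte(abs(rdf$bin_centers[first_nz] - a), rdf$bin_width)
  pk <- first_peak(rdf, smoothing_window = 1L, r_min = 0.3)
  expect_true(pk$found)
  expect_lte(abs(pk$r - a), rdf$bin_width)
})

test_that("CSR patterns give a flat lateral RDF near 1", {
  tr <- pattern_trajectory("poisson", seed = 99)
  rdf <- lateral_rdf(tr, seq_len(n_atoms(tr)), leaflet = "upper",
                     bin_width = 0.05, r_max = 3)
  sel <- rdf$bin_centers >= 0.5 & rdf$bin_centers <= 3
  mg <- mean(rdf$g[sel])
  se <- sd(colMeans(rdf$per_frame[sel, ])) / sqrt(rdf$n_frames)
  expect_lt(abs(mg - 1), 3 * se)
})

test_that("r_max beyond the minimum-image bound is rejected", {
  tr <- pattern_trajectory("poisson", seed = 1, n = 20, box = 10, frames = 1)
  expect_error(lateral_rdf(tr, 1:20, r_max = 6), "minimum-image")
})

test_that("first_peak finds principal maxima and rejects flat curves", {
  r <- (seq_len(60) - 0.5) * 0.05
  bump <- function(mu, amp = 1) amp * exp(-(r - mu)^2 / (2 * 0.05^2))
  pk <- first_peak(fake_rdf(1 + bump(0.55)))
  expect_true(pk$found)
  expect_lt(abs(pk$r - 0.55), 0.05 + 1e-12)

  expect_false(first_peak(fake_rdf(rep(1, 60)))$found)

  two <- first_peak(fake_rdf(1 + bump(0.5) + bump(0.9, 2)))
  expect_lt(abs(two$r - 0.5), 0.05 + 1e-12)

  # depletion shoulder below 1 is not a peak
  dep <- first_peak(fake_rdf(0.5 + bump(0.5, 0.3)))
  expect_false(dep$found)

  # monotone-decaying correlation: boundary bin accepted as truncated peak
  mono <- first_peak(fake_rdf(1 + 5 * exp(-r^2 / 0.36)))
  expect_true(mono$found)
  expect_equal(mono$r, 0.325)
})

test_that("density maps conserve counts and localize mass", {
  xyz <- matrix(rep(c(2.2, 3.3, 5), each = 4), 4, 3)
  atoms <- data.frame(resid = 1:4, resname = "CHL", name = "O3")
  tr <- trajectory(atoms, array(rep(xyz, 10), c(4, 3, 10)), c(10, 10, 10))
  dm <- density_map(tr, 1:4, grid_size = 10L)
  expect_equal(sum(dm$grid), 4L * 10L)
  expect_equal(max(dm$grid), 4L * 10L)  # all mass in one cell

  trp <- pattern_trajectory("poisson", seed = 12, n = 200, frames = 5)
  dmp <- density_map(trp, 1:200, grid_size = 20L)
  expect_equal(sum(dmp$grid), 200L * 5L)
  expect_error(density_map(trp, integer(0)), "empty selection")
})

test_that("Thomas clustering concentrates density relative to CSR", {
  gini <- function(x) {
    x <- sort(as.numeric(x))
    n <- length(x)
    2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  }
  g <- vapply(1:5, function(s) {
    gp <- gini(density_map(pattern_trajectory("poisson", s, n = 200,
                                              frames = 5),
                           1:200, grid_size = 20L)$grid)
    gt <- gini(density_map(pattern_trajectory("thomas", s, n = 200,
                                              frames = 5),
                           1:200, grid_size = 20L)$grid)
    c(gp, gt)
  }, numeric(2))
  expect_true(all(g[2, ] > g[1, ]))
})

test_that("pair energies hit the Lennard-Jones landmarks", {
  ff <- ff_params(data.frame(type = c("A", "B"), sigma = 0.3, epsilon = 0.5,
                             charge = 0))
  at <- data.frame(resid = 1:2, resname = "X", name = c("A", "B"))
  tr <- trajectory(at, array(c(0, 0.3, 0, 0, 0, 0), c(2, 3, 1)),
                   c(50, 50, 50))
  expect_equal(pair_interaction_energy(tr, 1, 2, ff)$mean, 0)
  tr2 <- trajectory(at, array(c(0, 0.3 * 2^(1 / 6), 0, 0, 0, 0),
                              c(2, 3, 1)), c(50, 50, 50))
  expect_equal(pair_interaction_energy(tr2, 1, 2, ff)$mean, -0.5,
               tolerance = 1e-12)
})

test_that("energies match the brute-force oracle, are symmetric and additive", {
  set.seed(7)
  n <- 40L
  names_ <- sample(c("A", "B"), n, TRUE)
  xyz <- matrix(runif(n * 3, 0, 5), n, 3)
  tr <- coords_trajectory(xyz, box = c(5, 5, 5), names = names_)
  ff <- ff_params(data.frame(type = c("A", "B"), sigma = c(0.3, 0.35),
                             epsilon = c(0.5, 0.2), charge = c(0.2, -0.1)))
  attr(ff, "box") <- c(5, 5, 5)
  ia <- 1:20; ib <- 21:40
  E <- pair_interaction_energy(tr, ia, ib, ff)$mean
  expect_lt(abs(E - brute_force_energy(xyz, names_, ia, ib, ff)), 1e-9)
  # symmetry
  expect_equal(pair_interaction_energy(tr, ib, ia, ff)$mean, E,
               tolerance = 1e-12)
  # additivity over a partition of B
  E1 <- pair_interaction_energy(tr, ia, 21:30, ff)$mean
  E2 <- pair_interaction_energy(tr, ia, 31:40, ff)$mean
  expect_equal(E1 + E2, E, tolerance = 1e-9)
  # cutoff removes exactly the terms beyond it
  ffc <- ff_params(ff$types, cutoff = 1.2)
  attr(ffc, "box") <- c(5, 5, 5)
  Ec <- pair_interaction_energy(tr, ia, ib, ffc)$mean
  expect_lt(abs(Ec - brute_force_energy(xyz, names_, ia, ib, ffc)), 1e-9)
})

test_that("energy evaluation enforces parameters and disjoint selections", {
  tr <- coords_trajectory(matrix(runif(9), 3, 3), names = c("A", "A", "Z"))
  ff <- ff_params(data.frame(type = "A", sigma = 0.3, epsilon = 0.1,
                             charge = 0))
  expect_error(pair_interaction_energy(tr, 1, 3, ff), "Z")
  expect_error(pair_interaction_energy(tr, 1:2, 2:3, ff), "disjoint")
})
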