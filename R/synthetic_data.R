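#' Configuration for the synthetic membrane generator
#'
#' Defines the toy bilayer emulated by [gen_membrane_system()]: a planar
#' two-leaflet DOPC:sterol bilayer (default 9:1, i.e. `sterol_fraction = 0.1`)
#' with five saponins per 200 lipids, mirroring the 200:5 lipid:saponin
#' composition of the simulated systems the analyses target. Molecules are
#' bead-level pseudo-molecules: each lipid is a phosphate bead (`P`) plus two
#' tail beads; each sterol is a hydroxyl-oxygen bead (`O3`) plus two body
#' beads; each saponin is an aglycone centroid (`AGL`), a linkage bead
#' (`LNK`), and a sugar-chain centroid (`SUG`). Saponin depth follows a
#' two-state (bound/unbound) Markov schedule.
#'
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @param n_lipids_per_leaflet lipids (DOPC + sterol) per leaflet.
#' @param sterol_fraction fraction of lipids that are sterols, in (0, 1).
#' @param box_xy lateral box edge (nm).
#' @param box_z box height (nm); the bilayer midplane sits at `box_z / 2`.
#' @param leaflet_z phosphate-plane offset from the midplane (nm).
#' @param clustering list with `mode` (`"poisson"` or `"thomas"`),
#'   `parent_intensity` (parents per nm^2) and `cluster_sd` (nm); controls the
#'   lateral sterol point pattern.
#' @param n_saponins saponin molecule count.
#' @param p_bound stationary probability of the bound state.
#' @param dwell_frames mean dwell time (frames) of the bound state.
#' @param n_frames number of trajectory frames.
#' @param jitter_sd per-frame Gaussian positional jitter (nm).
#' @param n_waters sparse water bead count (enough for hydrogen-bond and
#'   solvation tests; not liquid density).
#' @param saponin_angle aglycone-sugar angle at the linkage bead (degrees).
#' @param sterol_resname residue name used for sterol beads.
#' @return list of class `"membrane_config"`.
#' @export
membrane_config <- function(seed = 1L,
                            n_lipids_per_leaflet = 100L,
                            sterol_fraction = 0.1,
                            box_xy = 8,
                            box_z = 10,
                            leaflet_z = 2,
                            clustering = list(mode = "poisson",
                                              parent_intensity = 0.05,
                                              cluster_sd = 0.3),
                            n_saponins = 5L,
                            p_bound = 0.5,
                            dwell_frames = 10,
                            n_frames = 50L,
                            jitter_sd = 0.02,
                            n_waters = 200L,
                            saponin_angle = 120,
                            sterol_resname = "CHL") {
  stopifnot_scalar_prob(p_bound, "p_bound")
  if (sterol_fraction <= 0 || sterol_fraction >= 1)
    stop("'sterol_fraction' must lie in (0, 1)", call. = FALSE)
  if (box_xy <= 0 || box_z <= 0) stop("box dimensions must be > 0",
                                      call. = FALSE)
  if (n_frames < 1L) stop("'n_frames' must be >= 1", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
              sterol_fraction = sterol_fraction, box_xy = box_xy,
              box_z = box_z, leaflet_z = leaflet_z, clustering = clustering,
              n_saponins = as.integer(n_saponins), p_bound = p_bound,
              dwell_frames = dwell_frames, n_frames = as.integer(n_frames),
              jitter_sd = jitter_sd, n_waters = as.integer(n_waters),
              saponin_angle = saponin_angle,
              sterol_resname = sterol_resname)
  class(cfg) <- "membrane_config"
  cfg
}

#' Generate a 2D point pattern
#'
#' `"poisson"` draws `n` points uniformly and independently in the box
#' (complete spatial randomness); `"thomas"` draws Poisson-distributed cluster
#' parents with intensity `parent_intensity`, assigns the `n` offspring to
#' parents uniformly, displaces them by isotropic Gaussians of sd
#' `cluster_sd`, and wraps them periodically into the box (wrapping, not
#' rejection, so the realized density is exact).
#'
#' @param mode `"poisson"` or `"thomas"`.
#' @param n number of points (>= 2).
#' @param box_xy box edge (nm).
#' @param params list with `parent_intensity` (per nm^2) and `cluster_sd`
#'   (nm); used by the Thomas mode.
#' @param seed optional RNG seed (caller RNG state is restored).
#' @return `n x 2` matrix of coordinates in `[0, box_xy)`.
#' @export
gen_point_pattern <- function(mode, n, box_xy,
                              params = list(parent_intensity = 0.05,
                                            cluster_sd = 0.3),
                              seed = NULL) {
  if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
  run <- function() {
    if (mode == "poisson") {
      cbind(stats::runif(n, 0, box_xy), stats::runif(n, 0, box_xy))
    } else if (mode == "thomas") {
      np <- stats::rpois(1L, params$parent_intensity * box_xy^2)
      if (np < 1L) np <- 1L
      px <- stats::runif(np, 0, box_xy); py <- stats::runif(np, 0, box_xy)
      par <- sample.int(np, n, replace = TRUE)
      x <- (px[par] + stats::rnorm(n, 0, params$cluster_sd)) %% box_xy
      y <- (py[par] + stats::rnorm(n, 0, params$cluster_sd)) %% box_xy
      cbind(x, y)
    } else stop("unknown point-pattern mode: ", mode, call. = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Two-state bound/unbound Markov schedule with stationary P(bound) = p_bound
# and mean bound dwell time = dwell_frames; initial state drawn from the
# stationary distribution. Returns a logical n_mol x n_frames matrix.
markov_schedule <- function(n_mol, n_frames, p_bound, dwell_frames) {
  sched <- matrix(FALSE, n_mol, n_frames)
  if (p_bound >= 1) { sched[] <- TRUE; return(sched) }
  if (p_bound <= 0) return(sched)
  p_bu <- min(1, 1 / dwell_frames)               # bound -> unbound
  p_ub <- min(1, p_bu * p_bound / (1 - p_bound)) # unbound -> bound
  for (m in seq_len(n_mol)) {
    s <- stats::runif(1) < p_bound
    sched[m, 1] <- s
    if (n_frames > 1L) for (f in 2L:n_frames) {
      u <- stats::runif(1)
      s <- if (s) u >= p_bu else u < p_ub
      sched[m, f] <- s
    }
  }
  sched
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Builds a planar two-leaflet bead system per [membrane_config()]: phosphate
#' planes at `box_z/2 +/- leaflet_z`, sterol lateral positions drawn from the
#' configured point pattern, saponins whose aglycone bead sits 0.3 nm below
#' the upper phosphate plane when bound and 1.5 nm above it when unbound
#' (following a two-state Markov schedule), sparse water beads, and per-frame
#' Gaussian jitter. The returned ground truth carries the exact bound/unbound
#' schedule and per-frame sterol positions for parameter-recovery tests.
#'
#' @param cfg a [membrane_config()].
#' @return list with elements `trajectory` (a [trajectory()]) and
#'   `ground_truth` (list: `schedule` logical n_saponins x n_frames matrix,
#'   `bound_fraction_per_molecule`, `sterol_xy` array, `config`).
#' @export
gen_membrane_system <- function(cfg) {
  stopifnot(inherits(cfg, "membrane_config"))
  n_l <- cfg$n_lipids_per_leaflet
  if (n_l / cfg$box_xy^2 > 2.5)
    stop("box too small for the requested lipid count (", n_l, " per leaflet",
         " in ", cfg$box_xy, " x ", cfg$box_xy, " nm)", call. = FALSE)
  n_ster <- as.integer(round(cfg$sterol_fraction * n_l))
  n_dopc <- n_l - n_ster
  zmid <- cfg$box_z / 2
  plane <- c(upper = zmid + cfg$leaflet_z, lower = zmid - cfg$leaflet_z)

  with_seed(cfg$seed, {
    build_leaflet <- function(side) {
      sgn <- if (side == "upper") -1 else 1   # toward the midplane
      z0 <- plane[[side]]
      dopc_xy <- cbind(stats::runif(n_dopc, 0, cfg$box_xy),
                       stats::runif(n_dopc, 0, cfg$box_xy))
      ster_xy <- gen_point_pattern(cfg$clustering$mode, n_ster, cfg$box_xy,
                                   cfg$clustering)
      atoms <- data.frame(
        resname = c(rep("DOPC", 3L * n_dopc),
                    rep(cfg$sterol_resname, 3L * n_ster)),
        name = c(rep(c("P", "C1", "C2"), n_dopc),
                 rep(c("O3", "C1", "C2"), n_ster)),
        stringsAsFactors = FALSE)
      zoff <- c(0, 0.5, 1.0) * sgn
      xyz <- rbind(
        dopc_xy[rep(seq_len(n_dopc), each = 3L), , drop = FALSE],
        ster_xy[rep(seq_len(n_ster), each = 3L), , drop = FALSE])
      xyz <- cbind(xyz, z0 + rep(zoff, n_dopc + n_ster))
      mol <- rep(seq_len(n_dopc + n_ster), each = 3L)
      list(atoms = atoms, xyz = xyz, mol = mol, ster_xy = ster_xy)
    }
    up <- build_leaflet("upper")
    lo <- build_leaflet("lower")

    n_sap <- cfg$n_saponins
    sap_xy <- cbind(stats::runif(n_sap, 0, cfg$box_xy),
                    stats::runif(n_sap, 0, cfg$box_xy))
    schedule <- markov_schedule(n_sap, cfg$n_frames, cfg$p_bound,
                                cfg$dwell_frames)

    wat_xyz <- cbind(stats::runif(cfg$n_waters, 0, cfg$box_xy),
                     stats::runif(cfg$n_waters, 0, cfg$box_xy),
                     stats::runif(cfg$n_waters, 0, cfg$box_z))

    atoms <- rbind(
      data.frame(resid = rep(seq_len(n_l), each = 3L),
                 up$atoms, stringsAsFactors = FALSE),
      data.frame(resid = rep(n_l + seq_len(n_l), each = 3L),
                 lo$atoms, stringsAsFactors = FALSE),
      data.frame(resid = rep(2L * n_l + seq_len(n_sap), each = 3L),
                 resname = "SAP",
                 name = rep(c("AGL", "LNK", "SUG"), n_sap),
                 stringsAsFactors = FALSE),
      data.frame(resid = 2L * n_l + n_sap + seq_len(cfg$n_waters),
                 resname = "SOL", name = "OW", stringsAsFactors = FALSE))

    # saponin internal geometry: AGL at the schedule-driven depth, LNK 0.4 nm
    # along +x, SUG at 0.4 nm from LNK with the configured opening angle
    alpha <- (180 - cfg$saponin_angle) * pi / 180
    sug_off <- 0.4 * c(cos(alpha), 0, sin(alpha))
    sap_frame_xyz <- function(f) {
      agl_z <- ifelse(schedule[, f], plane[["upper"]] - 0.3,
                      plane[["upper"]] + 1.5)
      agl <- cbind(sap_xy, agl_z)
      lnk <- sweep(agl, 2, c(0.4, 0, 0), "+")
      sug <- sweep(lnk, 2, sug_off, "+")
      out <- matrix(NA_real_, 3L * n_sap, 3L)
      out[seq(1, 3 * n_sap, 3), ] <- agl
      out[seq(2, 3 * n_sap, 3), ] <- lnk
      out[seq(3, 3 * n_sap, 3), ] <- sug
      out
    }

    base_static <- rbind(up$xyz, lo$xyz)
    n_atoms_tot <- nrow(atoms)
    coords <- array(NA_real_, c(n_atoms_tot, 3L, cfg$n_frames))
    ster_idx_up <- which(atoms$resname == cfg$sterol_resname &
                           atoms$name == "O3")
    sterol_xy <- array(NA_real_, c(2L * n_ster, 2L, cfg$n_frames))
    for (f in seq_len(cfg$n_frames)) {
      frame <- rbind(base_static, sap_frame_xyz(f), wat_xyz)
      if (cfg$jitter_sd > 0)
        frame <- frame + matrix(stats::rnorm(length(frame), 0, cfg$jitter_sd),
                                nrow(frame), 3L)
      coords[, , f] <- frame
      sterol_xy[, , f] <- frame[ster_idx_up, 1:2]
    }
    traj <- trajectory(atoms, coords,
                       c(cfg$box_xy, cfg$box_xy, cfg$box_z),
                       time = (seq_len(cfg$n_frames) - 1) * 1.0)
    gt <- list(schedule = schedule,
               bound_fraction_per_molecule = rowMeans(schedule),
               sterol_xy = sterol_xy,
               config = cfg)
    list(trajectory = traj, ground_truth = gt)
  })
}

#' Generate a synthetic calcein-release fluorescence table
#'
#' Emits per concentration and replicate a fluorescence triplet (`I0` before
#' saponin, `I1` after saponin, `I2` after Triton X-100) constructed so that
#' the dilution-corrected release formula ([percent_release()]) recovers
#' `4PL(conc) * (1 + eps)` with multiplicative Gaussian noise
#' `eps ~ N(0, noise_sd)`. `I2` is fixed per replicate. Noisy releases
#' falling outside [0, 100] are clipped and flagged in the `clipped` column.
#'
#' @param true_4pl numeric `c(b, c, d, e)`: hill slope, lower and upper
#'   asymptote (percent), and EC50 (uM) of the generating curve (see
#'   [fourpl()]; `b < 0` gives a response increasing with concentration).
#' @param concentrations sorted non-negative concentrations (uM).
#' @param noise_sd multiplicative noise sd (fraction of the true release).
#' @param n_reps replicates per concentration.
#' @param dilution_factor assay dilution correction, default 0.89.
#' @param seed RNG seed.
#' @param composition label for the membrane composition column.
#' @param i0 baseline fluorescence before saponin (AU).
#' @param i2_base nominal full-lysis fluorescence (AU); each replicate draws
#'   its fixed `I2` uniformly within 10 percent of this value.
#' @return data.frame with columns `composition`, `concentration_uM`,
#'   `replicate`, `I0`, `I1`, `I2`, `clipped`; the generating parameters are
#'   attached as attribute `"true_4pl"`.
#' @export
gen_leakage_experiment <- function(true_4pl, concentrations, noise_sd = 0.05,
                                   n_reps = 3L, dilution_factor = 0.89,
                                   seed = 1L, composition = "LUV",
                                   i0 = 100, i2_base = 1000) {
  if (any(concentrations < 0) || is.unsorted(concentrations))
    stop("'concentrations' must be sorted and non-negative", call. = FALSE)
  if (dilution_factor <= 0 || dilution_factor > 1)
    stop("'dilution_factor' must lie in (0, 1]", call. = FALSE)
  stopifnot(length(true_4pl) == 4L)
  with_seed(seed, {
    i2_rep <- i2_base * stats::runif(n_reps, 0.9, 1.1)
    rows <- expand.grid(replicate = seq_len(n_reps),
                        concentration_uM = concentrations,
                        KEEP.OUT.ATTRS = FALSE)
    rel_true <- fourpl(rows$concentration_uM, true_4pl[1], true_4pl[2],
                       true_4pl[3], true_4pl[4])
    rel <- rel_true * (1 + stats::rnorm(nrow(rows), 0, noise_sd))
    clipped <- rel < 0 | rel > 100
    rel <- pmin(100, pmax(0, rel))
    i2 <- i2_rep[rows$replicate]
    i1 <- dilution_factor * i0 + rel / 100 * (i2 - dilution_factor * i0)
    out <- data.frame(composition = composition,
                      concentration_uM = rows$concentration_uM,
                      replicate = rows$replicate,
                      I0 = i0, I1 = i1, I2 = i2, clipped = clipped,
                      stringsAsFactors = FALSE)
    out <- out[order(out$concentration_uM, out$replicate), ]
    rownames(out) <- NULL
    attr(out, "true_4pl") <- stats::setNames(as.numeric(true_4pl),
                                             c("b", "c", "d", "e"))
    out
  })
}

#' Generate a synthetic cell-viability (PI uptake) table
#'
#' Per group and replicate, the propidium-iodide-positive count is drawn as
#' `Binomial(n_cells, lysis_prob)`.
#'
#' @param groups named numeric vector of true lysis probabilities per group.
#' @param n_cells total cells counted per replicate.
#' @param n_reps replicates per group.
#' @param seed RNG seed.
#' @return data.frame with columns `group`, `replicate`, `total_cells`,
#'   `pi_positive`; true probabilities attached as attribute `"true_lysis"`.
#' @export
gen_viability_experiment <- function(groups, n_cells = 20000L, n_reps = 5L,
                                     seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector", call. = FALSE)
  for (p in groups) stopifnot_scalar_prob(p, "lysis_prob")
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(groups), function(g) {
      data.frame(group = g, replicate = seq_len(n_reps),
                 total_cells = as.integer(n_cells),
                 pi_positive = stats::rbinom(n_reps, n_cells, groups[[g]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "true_lysis") <- groups
    out
  })
}
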