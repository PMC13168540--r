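#' Classify saponin membrane binding over a trajectory
#'
#' Per molecule and frame, the insertion depth is the z distance of the
#' aglycone centroid from the phosphate mean plane of the nearest leaflet,
#' signed so that negative values point toward the bilayer midplane. A frame
#' is `bound` when depth <= `depth_threshold` (default 0 nm, i.e. at or
#' below the phosphate plane). A molecule is `stably_inserted` when it is
#' bound in at least `stability_fraction` (default 0.8) of the frames in the
#' trailing evaluation window (default: last half of the trajectory). The
#' population bound fraction is the stably inserted count divided by the
#' number of molecules.
#'
#' @param traj a [trajectory()].
#' @param saponin_resname residue name identifying saponin molecules
#'   (grouped by `resid`).
#' @param phosphate_selection selection of phosphate atoms defining the two
#'   leaflet planes.
#' @param aglycone_name atom name of the aglycone bead(s) within a saponin.
#' @param depth_threshold bound/unbound depth cut (nm).
#' @param stability_fraction minimum bound fraction for stable insertion.
#' @param window trailing fraction of frames used for the summary (0, 1].
#' @return list of class `"binding_trace"`: `trace` data.frame (molecule,
#'   frame, depth, bound), `summary` data.frame (molecule, bound_fraction,
#'   stably_inserted), `population_fraction`, and the parameters used.
#' @export
classify_binding <- function(traj, saponin_resname = "SAP",
                             phosphate_selection,
                             aglycone_name = "AGL",
                             depth_threshold = 0,
                             stability_fraction = 0.8,
                             window = 0.5) {
  stopifnot(inherits(traj, "trajectory"), window > 0, window <= 1)
  pidx <- as_indices(phosphate_selection)
  sap <- which(traj$atoms$resname == saponin_resname)
  if (!length(sap)) stop("no saponin molecules with resname '",
                         saponin_resname, "'", call. = FALSE)
  mols <- split(sap, traj$atoms$resid[sap])
  agl <- lapply(mols, function(ix) ix[traj$atoms$name[ix] == aglycone_name])
  empty <- vapply(agl, length, 1L) == 0L
  if (any(empty))
    stop("saponin molecule(s) without aglycone atoms ('", aglycone_name,
         "'): resid ", paste(names(mols)[empty], collapse = ", "),
         call. = FALSE)

  nf <- n_frames(traj)
  nm <- length(mols)
  depth <- matrix(NA_real_, nm, nf)
  for (f in seq_len(nf)) {
    pz <- traj$coords[pidx, 3, f]
    mid <- mean(pz)
    plane_u <- mean(pz[pz >= mid]); plane_l <- mean(pz[pz < mid])
    for (m in seq_len(nm)) {
      zc <- mean(traj$coords[agl[[m]], 3, f])
      depth[m, f] <- if (abs(zc - plane_u) <= abs(zc - plane_l))
        zc - plane_u else plane_l - zc
    }
  }
  bound <- depth <= depth_threshold
  eval_frames <- seq.int(max(1L, nf - ceiling(window * nf) + 1L), nf)
  bf <- rowMeans(bound[, eval_frames, drop = FALSE])
  stable <- bf >= stability_fraction
  structure(list(
    trace = data.frame(molecule = rep(as.integer(names(mols)), nf),
                       frame = rep(seq_len(nf), each = nm),
                       depth = as.vector(depth), bound = as.vector(bound)),
    bound_matrix = bound,
    summary = data.frame(molecule = as.integer(names(mols)),
                         bound_fraction = bf, stably_inserted = stable),
    population_fraction = mean(stable),
    depth_threshold = depth_threshold,
    stability_fraction = stability_fraction,
    eval_frames = eval_frames), class = "binding_trace")
}

#' @export
print.binding_trace <- function(x, ...) {
  cat(sprintf("binding_trace: %d molecule(s), population bound fraction %.3f\n",
              nrow(x$summary), x$population_fraction))
  invisible(x)
}

#' Aglycone-sugar opening angle
#'
#' Angle (degrees, in [0, 180]) at the linkage atom between the vectors to
#' the aglycone centroid and to the sugar-chain centroid; ~180 deg is an
#' extended saponin conformation, 60-135 deg a folded/bent one.
#'
#' @param frame a frame from [traj_frame()].
#' @param linkage_atom index of the linkage atom.
#' @param aglycone_selection,sugar_selection selections for the two moieties.
#' @return angle in degrees.
#' @export
aglycone_sugar_angle <- function(frame, linkage_atom, aglycone_selection,
                                 sugar_selection) {
  ia <- as_indices(aglycone_selection); is_ <- as_indices(sugar_selection)
  il <- as_indices(linkage_atom)
  if (!length(ia) || !length(is_)) stop("empty moiety selection",
                                        call. = FALSE)
  lnk <- colMeans(frame$xyz[il, , drop = FALSE])
  v1 <- colMeans(frame$xyz[ia, , drop = FALSE]) - lnk
  v2 <- colMeans(frame$xyz[is_, , drop = FALSE]) - lnk
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("degenerate geometry: a moiety centroid coincides with the linkage",
         call. = FALSE)
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# Deterministic Fibonacci sphere: n approximately uniform unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples a deterministic Fibonacci sphere of `n_sphere_points` on each
#' atom's expanded sphere (vdW radius + probe) and keeps the fraction of
#' points not strictly inside any other expanded sphere; per-atom SASA is
#' that fraction times `4 pi (r_i + probe)^2`.
#'
#' @param xyz `n x 3` coordinate matrix in Angstrom (use `coords_unit =
#'   "nm"` for trajectory frames).
#' @param radii van der Waals radii in Angstrom: either a vector parallel to
#'   the rows of `xyz` or a named vector looked up by `atom_names`.
#' @param atom_names atom names used for radius lookup when `radii` is named.
#' @param probe_radius probe radius (Angstrom, default 1.4).
#' @param n_sphere_points test points per atom (default 960).
#' @param coords_unit `"angstrom"` (default) or `"nm"`.
#' @return list of class `"sasa_result"`: `total` (A^2), `per_atom` (A^2).
#' @export
sasa <- function(xyz, radii, atom_names = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L, coords_unit = c("angstrom", "nm")) {
  coords_unit <- match.arg(coords_unit)
  xyz <- as.matrix(xyz)
  if (coords_unit == "nm") xyz <- xyz * 10
  n <- nrow(xyz)
  if (!is.null(names(radii))) {
    if (is.null(atom_names))
      stop("'atom_names' required when 'radii' is a named table",
           call. = FALSE)
    m <- match(atom_names, names(radii))
    if (anyNA(m))
      stop("missing radius for atom type(s): ",
           paste(unique(atom_names[is.na(m)]), collapse = ", "),
           call. = FALSE)
    radii <- unname(radii[m])
  }
  if (length(radii) == 1L) radii <- rep(radii, n)
  stopifnot(length(radii) == n)
  pts <- fibonacci_sphere(n_sphere_points)
  R <- radii + probe_radius
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < R[i] + R & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj >= R[j]^2
    }
    per_atom[i] <- mean(accessible) * 4 * pi * R[i]^2
  }
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points), class = "sasa_result")
}

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the common geometric convention (donor-acceptor distance
#' <= 3.5 Angstrom = 0.35 nm, donor-hydrogen-acceptor angle >= 150 deg); the
#' thresholds are conventions, exposed as configuration. When no hydrogen
#' positions are available a distance-only heavy-atom fallback applies,
#' flagged in the result.
#'
#' @param max_DA_distance maximum donor-acceptor distance (nm).
#' @param min_DHA_angle minimum D-H...A angle (degrees).
#' @return list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_DA_distance = 0.35, min_DHA_angle = 150) {
  stopifnot(max_DA_distance > 0, min_DHA_angle > 0, min_DHA_angle <= 180)
  structure(list(max_DA_distance = max_DA_distance,
                 min_DHA_angle = min_DHA_angle), class = "hbond_criteria")
}

#' Count hydrogen bonds in a frame
#'
#' Counts (donor, hydrogen, acceptor) triples with donor-acceptor distance
#' within `criteria$max_DA_distance` and D-H...A angle (at the hydrogen) of
#' at least `criteria$min_DHA_angle`. Distances honor the 3D minimum-image
#' convention. Without `hydrogens`, a distance-only fallback counts
#' donor-acceptor contacts and the result is flagged `mode = "distance-only"`.
#'
#' @param frame a frame from [traj_frame()].
#' @param donor_selection,acceptor_selection selections of heavy atoms.
#' @param hydrogens optional list, parallel to the donor indices, of
#'   hydrogen atom indices attached to each donor.
#' @param criteria an [hbond_criteria()].
#' @return integer count with attribute `"mode"` (`"geometric"` or
#'   `"distance-only"`).
#' @export
count_hbonds <- function(frame, donor_selection, acceptor_selection,
                         hydrogens = NULL, criteria = hbond_criteria()) {
  don <- as_indices(donor_selection); acc <- as_indices(acceptor_selection)
  if (!length(don) || !length(acc)) {
    warning("no donors or acceptors selected", call. = FALSE)
    return(structure(0L, mode = if (is.null(hydrogens)) "distance-only"
                     else "geometric"))
  }
  box <- frame$box
  dvec <- function(a, b) {  # minimum-image b - a
    if (!length(b)) return(matrix(numeric(0), 0L, 3L))
    d <- frame$xyz[b, , drop = FALSE] -
      matrix(frame$xyz[a, ], nrow = length(b), ncol = 3, byrow = TRUE)
    for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
    d
  }
  count <- 0L
  for (di in seq_along(don)) {
    D <- don[di]
    da <- dvec(D, acc)
    ok <- sqrt(rowSums(da^2)) <= criteria$max_DA_distance &
      acc != D
    if (is.null(hydrogens)) {
      count <- count + sum(ok)
    } else {
      hs <- hydrogens[[di]]
      for (H in hs) {
        hd <- dvec(H, D)          # H -> D
        ha <- dvec(H, acc[ok])    # H -> A
        if (!nrow(ha)) next
        cosang <- (ha %*% t(hd)) /
          (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        count <- count + sum(ang >= criteria$min_DHA_angle)
      }
    }
  }
  structure(as.integer(count),
            mode = if (is.null(hydrogens)) "distance-only" else "geometric")
}

#' Per-frame hydrogen-bond series over a trajectory
#'
#' @param traj a [trajectory()].
#' @param ... passed to [count_hbonds()].
#' @return integer vector, one count per frame.
#' @export
hbond_series <- function(traj, ...) {
  vapply(seq_len(n_frames(traj)),
         function(f) as.integer(count_hbonds(traj_frame(traj, f), ...)),
         integer(1))
}

#' Saponin-water solvation (interaction) energy
#'
#' Nonbonded Lennard-Jones + Coulomb interaction energy between a saponin
#' selection and the surrounding water, reported as the frame mean with a
#' block-averaged SE. This is an interaction energy, not a free-energy
#' estimate.
#'
#' @param traj a [trajectory()].
#' @param saponin_selection,water_selection disjoint selections.
#' @param ff an [ff_params()].
#' @param frames optional frame subset.
#' @return an `"energy_series"` (see [pair_interaction_energy()]).
#' @export
solvation_energy <- function(traj, saponin_selection, water_selection, ff,
                             frames = NULL) {
  pair_interaction_energy(traj, saponin_selection, water_selection, ff,
                          frames = frames)
}
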