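#' Assign bilayer leaflets from phosphate positions
#'
#' The bilayer midplane is estimated as the mean z of the phosphate atoms;
#' phosphates above the midplane belong to the upper leaflet, below to the
#' lower (ties go to the upper leaflet by convention).
#'
#' @param frame a frame from [traj_frame()].
#' @param phosphate_selection selection (or index vector) of phosphate atoms;
#'   at least two atoms spanning two leaflets.
#' @return list with `midplane_z` (nm) and `labels`, a character vector
#'   (`"upper"`/`"lower"`) parallel to the phosphate selection.
#' @export
assign_leaflets <- function(frame, phosphate_selection) {
  idx <- as_indices(phosphate_selection)
  if (length(idx) < 2L) stop("need at least 2 phosphate atoms", call. = FALSE)
  z <- frame$xyz[idx, 3]
  if (diff(range(z)) < 1e-9)
    stop("degenerate bilayer: all phosphates lie in one plane", call. = FALSE)
  mid <- mean(z)
  list(midplane_z = mid,
       labels = ifelse(z >= mid, "upper", "lower"))
}

#' Lateral (2D) radial distribution function
#'
#' Computes the in-plane sterol-sterol (or any selection) pair correlation
#' within a leaflet: distances use only the x and y components under the
#' minimum-image convention in x and y (the bilayer normal is not periodic in
#' analysis terms). Per frame, unordered pair counts in annuli
#' `[r, r + dr)` are normalized by `N * rho * pi * ((r+dr)^2 - r^2) / 2` with
#' the reference density `rho = (N - 1) / (Lx * Ly)` (self pair excluded),
#' then averaged over frames. `leaflet = "both"` pools the two leaflets but
#' never counts inter-leaflet pairs.
#'
#' @param traj a [trajectory()].
#' @param selection atoms entering the RDF (e.g. sterol hydroxyl oxygens).
#' @param leaflet `"upper"`, `"lower"`, or `"both"`.
#' @param bin_width annulus width (nm).
#' @param r_max maximum radius (nm); must not exceed `min(Lx, Ly) / 2`
#'   (minimum-image validity). Defaults to that bound rounded down to a bin.
#' @param frame_range optional integer range of frames, e.g. `1:50`.
#' @param phosphate_selection optional phosphate selection used to locate the
#'   midplane; when omitted the mean z of `selection` is used.
#' @return object of class `"rdf_result"`: `bin_centers`, `g` (frame
#'   average), `g_se` (per-bin SE over frames), `per_frame` matrix,
#'   `bin_width`, `r_max`, `n_frames`, `leaflet`, `surface_density` (mean
#'   points per nm^2 per leaflet).
#' @export
lateral_rdf <- function(traj, selection, leaflet = c("both", "upper", "lower"),
                        bin_width = 0.05, r_max = NULL, frame_range = NULL,
                        phosphate_selection = NULL) {
  leaflet <- match.arg(leaflet)
  idx <- as_indices(selection)
  frames <- frame_range %||% seq_len(n_frames(traj))
  stopifnot(all(frames >= 1L), all(frames <= n_frames(traj)))
  Lx <- traj$box[frames[1], 1]; Ly <- traj$box[frames[1], 2]
  half_min <- min(Lx, Ly) / 2
  if (is.null(r_max)) r_max <- floor(half_min / bin_width) * bin_width
  if (r_max > half_min + 1e-9)
    stop("r_max (", r_max, " nm) exceeds min(Lx, Ly)/2: minimum-image ",
         "convention violated", call. = FALSE)
  n_bins <- as.integer(ceiling(r_max / bin_width - 1e-9))
  per_frame <- matrix(NA_real_, n_bins, length(frames))
  dens <- numeric(length(frames))

  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- matrix(traj$coords[idx, , f], ncol = 3)
    box <- traj$box[f, ]
    mid <- if (is.null(phosphate_selection)) mean(xyz[, 3]) else
      mean(traj$coords[as_indices(phosphate_selection), 3, f])
    groups <- switch(leaflet,
      upper = list(xyz[xyz[, 3] >= mid, 1:2, drop = FALSE]),
      lower = list(xyz[xyz[, 3] < mid, 1:2, drop = FALSE]),
      both = list(xyz[xyz[, 3] >= mid, 1:2, drop = FALSE],
                  xyz[xyz[, 3] < mid, 1:2, drop = FALSE]))
    groups <- Filter(function(g) nrow(g) >= 2L, groups)
    if (!length(groups))
      stop("fewer than 2 selected atoms in the requested leaflet (frame ",
           f, ")", call. = FALSE)
    counts <- numeric(n_bins); expected <- numeric(n_bins); npts <- 0L
    edges_sq_area <- pi * ((seq_len(n_bins) * bin_width)^2 -
                           ((seq_len(n_bins) - 1L) * bin_width)^2)
    for (g in groups) {
      N <- nrow(g)
      dx <- min_image(outer(g[, 1], g[, 1], "-"), box[1])
      dy <- min_image(outer(g[, 2], g[, 2], "-"), box[2])
      r <- sqrt(dx^2 + dy^2)[upper.tri(dx)]
      bin <- floor(r / bin_width) + 1L
      keep <- bin >= 1L & bin <= n_bins
      counts <- counts + tabulate(bin[keep], nbins = n_bins)
      rho <- (N - 1) / (box[1] * box[2])
      expected <- expected + N * rho * edges_sq_area / 2
      npts <- npts + N
    }
    per_frame[, k] <- counts / expected
    dens[k] <- npts / (box[1] * box[2] * length(groups))
  }
  g_mean <- rowMeans(per_frame)
  g_se <- if (length(frames) > 1L)
    apply(per_frame, 1L, stats::sd) / sqrt(length(frames)) else
    rep(NA_real_, n_bins)
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) * bin_width,
                 g = g_mean, g_se = g_se, per_frame = per_frame,
                 bin_width = bin_width, r_max = r_max,
                 n_frames = length(frames), leaflet = leaflet,
                 surface_density = mean(dens)),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins to %.2f nm, %d frame(s), leaflet %s\n",
              length(x$g), x$r_max, x$n_frames, x$leaflet))
  invisible(x)
}

#' First peak of a lateral RDF
#'
#' Smooths g(r) with a centered moving average (odd window) and returns the
#' smallest radius at or beyond `r_min` holding a local maximum with
#' smoothed g > 1 (the principal correlation maximum; depletion shoulders
#' below 1 are excluded). Ties resolve to the smallest radius. The first
#' searched bin can carry a genuine maximum truncated by `r_min` (clustered
#' point patterns without excluded volume have monotonically decaying g); it
#' is accepted only when the smoothed curve also decreases strictly across
#' the following full smoothing window, which keeps boundary noise in
#' unstructured (CSR) data from masquerading as a peak.
#'
#' @param rdf an `"rdf_result"` from [lateral_rdf()].
#' @param smoothing_window odd moving-average window in bins (default 5).
#' @param r_min smallest radius considered (nm, default 0.3).
#' @return list of class `"rdf_peak"`: `found` (logical), `r` (nm or NA),
#'   `g` (smoothed height or NA), `index` (bin index or NA).
#' @export
first_peak <- function(rdf, smoothing_window = 5L, r_min = 0.3) {
  stopifnot(inherits(rdf, "rdf_result"))
  gs <- moving_average(rdf$g, smoothing_window)
  r <- rdf$bin_centers
  n <- length(gs)
  searched <- which(r >= r_min)
  no_peak <- structure(list(found = FALSE, r = NA_real_, g = NA_real_,
                            index = NA_integer_), class = "rdf_peak")
  if (!length(searched)) return(no_peak)
  j0 <- searched[1]
  run <- min(smoothing_window - 1L, n - j0)
  boundary_ok <- gs[j0] > 1 && run >= 1L &&
    all(diff(gs[j0:(j0 + run)]) < 0)
  for (i in searched) {
    if (gs[i] <= 1) next
    if (i == j0) {
      if (boundary_ok)
        return(structure(list(found = TRUE, r = r[i], g = gs[i], index = i),
                         class = "rdf_peak"))
    } else if (i == n) {
      if (gs[i] > gs[i - 1L])
        return(structure(list(found = TRUE, r = r[i], g = gs[i], index = i),
                         class = "rdf_peak"))
    } else if (gs[i] > gs[i - 1L] && gs[i] >= gs[i + 1L]) {
      return(structure(list(found = TRUE, r = r[i], g = gs[i], index = i),
                       class = "rdf_peak"))
    }
  }
  no_peak
}

#' @export
print.rdf_peak <- function(x, ...) {
  if (x$found) cat(sprintf("rdf_peak: r = %.3f nm (g = %.3f)\n", x$r, x$g))
  else cat("rdf_peak: no qualifying maximum\n")
  invisible(x)
}

#' Cumulative 2D density map
#'
#' Accumulates a 2D histogram of the (x, y) positions of the selected atoms
#' over a frame window (coordinates wrapped into the box). The total count is
#' exactly `n_selected * n_frames_in_window`.
#'
#' @param traj a [trajectory()].
#' @param selection atoms to histogram (e.g. sterol hydroxyl oxygens).
#' @param grid_size number of bins along each axis.
#' @param frame_window integer vector of frames (default: all).
#' @return list of class `"density_map"`: `grid` (counts matrix, x by y),
#'   `x_edges`, `y_edges` (nm), `window`.
#' @export
density_map <- function(traj, selection, grid_size = 50L,
                        frame_window = NULL) {
  idx <- as_indices(selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  frames <- frame_window %||% seq_len(n_frames(traj))
  stopifnot(all(frames >= 1L), all(frames <= n_frames(traj)))
  Lx <- traj$box[frames[1], 1]; Ly <- traj$box[frames[1], 2]
  grid <- matrix(0L, grid_size, grid_size)
  for (f in frames) {
    x <- traj$coords[idx, 1, f] %% Lx
    y <- traj$coords[idx, 2, f] %% Ly
    ix <- pmin(grid_size, floor(x / Lx * grid_size) + 1L)
    iy <- pmin(grid_size, floor(y / Ly * grid_size) + 1L)
    for (k in seq_along(ix)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  }
  structure(list(grid = grid,
                 x_edges = seq(0, Lx, length.out = grid_size + 1L),
                 y_edges = seq(0, Ly, length.out = grid_size + 1L),
                 window = frames),
            class = "density_map")
}

#' Nonbonded force-field parameters
#'
#' Per-atom-type Lennard-Jones and charge parameters for
#' [pair_interaction_energy()]. Pair parameters use Lorentz-Berthelot
#' combining (arithmetic-mean sigma, geometric-mean epsilon); electrostatics
#' use the Coulomb constant 138.935 kJ mol^-1 nm e^-2.
#'
#' @param types data.frame with columns `type` (matched against atom names),
#'   `sigma` (nm), `epsilon` (kJ/mol), `charge` (e).
#' @param cutoff pair cutoff (nm); `Inf` for no cutoff.
#' @param dielectric relative dielectric constant.
#' @return list of class `"ff_params"`.
#' @export
ff_params <- function(types, cutoff = Inf, dielectric = 1) {
  stopifnot(is.data.frame(types),
            all(c("type", "sigma", "epsilon", "charge") %in% names(types)))
  if (any(types$sigma < 0) || any(types$epsilon < 0))
    stop("sigma and epsilon must be >= 0", call. = FALSE)
  if (!(cutoff > 0)) stop("cutoff must be > 0 (or Inf)", call. = FALSE)
  structure(list(types = types, cutoff = cutoff, dielectric = dielectric,
                 k_coulomb = 138.935), class = "ff_params")
}

ff_lookup <- function(ff, atom_names) {
  m <- match(atom_names, ff$types$type)
  if (anyNA(m)) {
    missing <- unique(atom_names[is.na(m)])
    stop("missing force-field parameters for atom type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ff$types[m, , drop = FALSE]
}

# Energy between two coordinate sets for a single frame (nm, kJ/mol).
pair_energy_frame <- function(xyzA, xyzB, parA, parB, box, ff) {
  dx <- min_image(outer(xyzA[, 1], xyzB[, 1], "-"), box[1])
  dy <- min_image(outer(xyzA[, 2], xyzB[, 2], "-"), box[2])
  dz <- min_image(outer(xyzA[, 3], xyzB[, 3], "-"), box[3])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  sig <- outer(parA$sigma, parB$sigma, "+") / 2
  eps <- sqrt(outer(parA$epsilon, parB$epsilon))
  qq <- outer(parA$charge, parB$charge)
  keep <- r < ff$cutoff
  r <- r[keep]; sig <- sig[keep]; eps <- eps[keep]; qq <- qq[keep]
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6)) + ff$k_coulomb * sum(qq / (ff$dielectric * r))
}

#' Pairwise nonbonded interaction energy between two selections
#'
#' Sums Lennard-Jones and Coulomb terms over all cross pairs closer than the
#' cutoff, under the full 3D minimum-image convention:
#' `E = sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6) + k_C q_i q_j / (eps_r r)`.
#' Reported per frame with the mean and a block-averaged (5 blocks) standard
#' error over frames.
#'
#' @param traj a [trajectory()] (or a single frame from [traj_frame()]).
#' @param selA,selB disjoint selections.
#' @param ff an [ff_params()] covering every atom name in the selections.
#' @param frames optional frame subset.
#' @return list of class `"energy_series"`: `series` (kJ/mol per frame),
#'   `mean`, `se`, `n_frames`.
#' @export
pair_interaction_energy <- function(traj, selA, selB, ff, frames = NULL) {
  stopifnot(inherits(ff, "ff_params"))
  ia <- as_indices(selA); ib <- as_indices(selB)
  if (length(intersect(ia, ib)))
    stop("selections must be disjoint", call. = FALSE)
  if (!inherits(traj, "trajectory")) {           # single frame
    traj <- trajectory(traj$atoms, traj$xyz, traj$box)
  }
  frames <- frames %||% seq_len(n_frames(traj))
  parA <- ff_lookup(ff, traj$atoms$name[ia])
  parB <- ff_lookup(ff, traj$atoms$name[ib])
  series <- vapply(frames, function(f) {
    pair_energy_frame(matrix(traj$coords[ia, , f], ncol = 3),
                      matrix(traj$coords[ib, , f], ncol = 3),
                      parA, parB, traj$box[f, ], ff)
  }, numeric(1))
  structure(list(series = series, mean = mean(series),
                 se = block_se(series), n_frames = length(frames)),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("energy_series: mean %.4f kJ/mol (SE %.4f, %d frame(s))\n",
              x$mean, if (is.na(x$se)) 0 else x$se, x$n_frames))
  invisible(x)
}
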