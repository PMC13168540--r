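# Shared fixture builders (all fixtures generated in code).

# Trajectory whose frames are independent 2D point patterns at fixed z,
# for lateral RDF statistics.
pattern_trajectory <- function(mode, seed, n = 400, box = 20, frames = 50,
                               params = list(parent_intensity = 0.05,
                                             cluster_sd = 0.3)) {
  atoms <- data.frame(resid = seq_len(n), resname = "CHL", name = "O3",
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(n, 3, frames))
  for (f in seq_len(frames)) {
    xy <- gen_point_pattern(mode, n, box, params, seed = seed * 1000L + f)
    coords[, , f] <- cbind(xy, 1)
  }
  trajectory(atoms, coords, c(box, box, 10))
}

# Minimal single-frame trajectory from a coordinate matrix.
coords_trajectory <- function(xyz, box = c(50, 50, 50), names = NULL,
                              resname = "X") {
  n <- nrow(xyz)
  atoms <- data.frame(resid = seq_len(n), resname = resname,
                      name = names %||% rep("A", n),
                      stringsAsFactors = FALSE)
  trajectory(atoms, array(xyz, c(n, 3, 1)), box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled rdf_result for peak-detection tests.
fake_rdf <- function(g, bin_width = 0.05) {
  structure(list(bin_centers = (seq_along(g) - 0.5) * bin_width, g = g,
                 g_se = rep(0, length(g)),
                 per_frame = matrix(g, ncol = 1), bin_width = bin_width,
                 r_max = length(g) * bin_width, n_frames = 1L,
                 leaflet = "both", surface_density = NA_real_),
            class = "rdf_result")
}

# Brute-force nonbonded energy oracle (plain double loop, 3D minimum image).
brute_force_energy <- function(xyz, names, ia, ib, ff) {
  E <- 0
  for (i in ia) for (j in ib) {
    d <- xyz[i, ] - xyz[j, ]
    d <- d - attr(ff, "box") * round(d / attr(ff, "box"))
    r <- sqrt(sum(d^2))
    if (r >= ff$cutoff) next
    pi_ <- ff$types[match(names[i], ff$types$type), ]
    pj <- ff$types[match(names[j], ff$types$type), ]
    sig <- (pi_$sigma + pj$sigma) / 2
    eps <- sqrt(pi_$epsilon * pj$epsilon)
    E <- E + 4 * eps * ((sig / r)^12 - (sig / r)^6) +
      ff$k_coulomb * pi_$charge * pj$charge / (ff$dielectric * r)
  }
  E
}
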