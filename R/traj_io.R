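#' Construct a trajectory object
#'
#' A trajectory holds an atom table (constant topology), per-frame coordinates
#' in nanometres, and per-frame orthorhombic box vectors. All analysis in the
#' package operates on this container; GRO and XYZ readers/writers convert at
#' the I/O boundary (GRO stores nm, XYZ stores Angstrom).
#'
#' @param atoms data.frame with columns `resid` (integer), `resname`,
#'   `name` (atom name); one row per atom, order defines atom indices (1-based).
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, nm.
#' @param box numeric matrix `n_frames x 3` of box lengths (Lx, Ly, Lz), nm,
#'   or a length-3 vector recycled to all frames.
#' @param time optional numeric vector of frame times (ps).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(atoms, coords, box, time = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("resid", "resname", "name") %in% names(atoms)))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == nf, ncol(box) == 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (any(box <= 0)) stop("box lengths must be > 0", call. = FALSE)
  structure(list(
    atoms = atoms, coords = coords, box = box,
    time = time %||% rep(NA_real_, nf),
    topology = paste(atoms$resid, atoms$resname, atoms$name,
                     sep = ":", collapse = "|")
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frame(s), box %s nm\n",
              n_atoms(x), n_frames(x),
              paste(sprintf("%.3f", x$box[1, ]), collapse = " x ")))
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract a single frame
#'
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return list with `atoms`, `xyz` (n x 3 matrix, nm), `box` (length 3, nm),
#'   `time` (ps or NA).
#' @export
traj_frame <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(atoms = traj$atoms, xyz = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ], time = traj$time[i])
}

# ---- GRO -------------------------------------------------------------------

#' Read a (multi-frame) GRO coordinate file
#'
#' Parses the fixed-width GROMACS GRO dialect: title line, atom count line,
#' atom records (`resid` 5, `resname` 5, atom `name` 5, atom number 5, then
#' three 8.3 coordinate fields in nm), and a final box line. Repeated
#' title/count blocks are read as successive frames. Only orthorhombic boxes
#' are supported; box lines carrying nonzero triclinic off-diagonal components
#' are rejected rather than silently mis-read.
#'
#' @param path file path.
#' @return a [trajectory()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0)
  atoms <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    title <- lines[pos]
    if (pos + 1L > length(lines))
      stop("GRO parse error at line ", pos, ": missing atom count line",
           call. = FALSE)
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat) || nat < 1L)
      stop("GRO parse error at line ", pos + 1L, ": bad atom count",
           call. = FALSE)
    last_atom <- pos + 1L + nat
    if (last_atom + 1L > length(lines))
      stop("GRO parse error: atom count line ", pos + 1L, " declares ", nat,
           " atoms but the file ends early", call. = FALSE)
    rec <- lines[(pos + 2L):last_atom]
    if (any(nchar(rec) < 44L)) {
      bad <- which(nchar(rec) < 44L)[1] + pos + 1L
      stop("GRO parse error at line ", bad, ": atom record too short",
           call. = FALSE)
    }
    resid <- suppressWarnings(as.integer(substr(rec, 1L, 5L)))
    resname <- trimws(substr(rec, 6L, 10L))
    name <- trimws(substr(rec, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(rec, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(rec, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(rec, 37L, 44L)))
    if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1] + pos + 1L
      stop("GRO parse error at line ", bad, ": malformed atom record",
           call. = FALSE)
    }
    boxf <- suppressWarnings(as.numeric(strsplit(trimws(lines[last_atom + 1L]),
                                                 "\\s+")[[1]]))
    if (length(boxf) < 3L || anyNA(boxf))
      stop("GRO parse error at line ", last_atom + 1L, ": bad box line",
           call. = FALSE)
    if (length(boxf) > 3L && any(abs(boxf[-(1:3)]) > 0))
      stop("unsupported GRO box: triclinic off-diagonal components present",
           call. = FALSE)
    this_atoms <- data.frame(resid = resid, resname = resname, name = name,
                             stringsAsFactors = FALSE)
    if (is.null(atoms)) atoms <- this_atoms
    else if (!identical(atoms, this_atoms))
      stop("GRO frames do not share a constant topology", call. = FALSE)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- boxf[1:3]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
                      else NA_real_)
    pos <- last_atom + 2L
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("empty GRO file: ", path, call. = FALSE)
  coords <- array(unlist(frames), c(nrow(atoms), 3L, length(frames)))
  trajectory(atoms, coords, do.call(rbind, boxes), time = times)
}

#' Write a trajectory as a fixed-width (multi-frame) GRO file
#'
#' Inverse of [read_gro()] up to the format precision of 0.001 nm.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_atoms(traj) < 1L) stop("empty trajectory", call. = FALSE)
  if (any(traj$coords >= 10000 | traj$coords <= -1000))
    stop("coordinates exceed the 8.3 GRO field width", call. = FALSE)
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    tm <- traj$time[f]
    writeLines(sprintf("sapomem frame %d%s", f,
                       if (is.na(tm)) "" else sprintf(", t= %.3f", tm)), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$resid %% 100000L, at$resname, at$name,
                       seq_len(nrow(at)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1], traj$box[f, 2],
                       traj$box[f, 3]), con)
  }
  invisible(path)
}

# ---- XYZ -------------------------------------------------------------------

#' Read a (multi-frame) XYZ coordinate file
#'
#' XYZ files store Angstrom; coordinates are converted to nm on input. XYZ
#' carries no box, so the box must either be supplied via `box` (nm) or be
#' encoded in the comment line as `box=Lx,Ly,Lz` (Angstrom).
#'
#' @param path file path.
#' @param box optional length-3 orthorhombic box (nm) applied to all frames.
#' @return a [trajectory()].
#' @export
read_xyz <- function(path, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); nat0 <- NA_integer_
  names0 <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop("XYZ parse error at line ", pos, ": bad atom count", call. = FALSE)
    if (is.na(nat0)) nat0 <- nat
    else if (nat != nat0)
      stop("inconsistent atom counts across XYZ frames (", nat0, " vs ", nat,
           ")", call. = FALSE)
    comment <- lines[pos + 1L]
    bm <- regmatches(comment,
                     regexpr("box=\\s*[-0-9.eE+]+\\s*,\\s*[-0-9.eE+]+\\s*,\\s*[-0-9.eE+]+",
                             comment))
    frame_box <- if (length(bm)) {
      as.numeric(strsplit(sub("box=\\s*", "", bm), "\\s*,\\s*")[[1]]) / 10
    } else if (!is.null(box)) box else
      stop("XYZ file carries no box and none was supplied", call. = FALSE)
    rec <- lines[(pos + 2L):(pos + 1L + nat)]
    tok <- strsplit(trimws(rec), "\\s+")
    if (any(lengths(tok) < 4L))
      stop("XYZ parse error: malformed atom record near line ", pos + 2L,
           call. = FALSE)
    nm <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3))) / 10
    if (is.null(names0)) names0 <- nm
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- frame_box
    pos <- pos + 2L + nat
  }
  atoms <- data.frame(resid = seq_along(names0), resname = "MOL",
                      name = names0, stringsAsFactors = FALSE)
  coords <- array(unlist(frames), c(nat0, 3L, length(frames)))
  trajectory(atoms, coords, do.call(rbind, boxes))
}

#' Write a trajectory as a (multi-frame) XYZ file
#'
#' Coordinates are written in Angstrom; the box is encoded in the comment line
#' as `box=Lx,Ly,Lz` (Angstrom) so [read_xyz()] can recover it.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("%d", n_atoms(traj)), con)
    writeLines(sprintf("box=%.6f,%.6f,%.6f", traj$box[f, 1] * 10,
                       traj$box[f, 2] * 10, traj$box[f, 3] * 10), con)
    xyz <- traj$coords[, , f, drop = TRUE] * 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", traj$atoms$name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
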