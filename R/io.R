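#' Read a PDB structure into a molecular system
#'
#' Parses ATOM/HETATM records via bio3d. Alternate locations are resolved by
#' keeping, within each (chain, residue, atom name) group, the record with
#' the highest occupancy; ties keep the first listed. Atom order is preserved
#' from the file.
#'
#' @param path path to a PDB file
#' @param dialect currently only `"pdb"`
#' @return a [molecular_system()]
#' @export
read_structure <- function(path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  if (nrow(a) == 0L) stop("no ATOM/HETATM records in ", path)

  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- a$elesy
  need <- is.na(elem) | trimws(elem) == ""
  elem[need] <- guess_element(a$elety[need])
  elem <- toupper(trimws(elem))

  keep <- resolve_altloc(a$alt, chain, a$resno, a$elety, a$o)
  atoms <- data.frame(
    serial = a$eleno[keep],
    type = a$type[keep],
    atom_name = trimws(a$elety[keep]),
    residue_name = trimws(a$resid[keep]),
    residue_number = a$resno[keep],
    chain_id = chain[keep],
    element = elem[keep],
    x = a$x[keep], y = a$y[keep], z = a$z[keep],
    stringsAsFactors = FALSE
  )
  molecular_system(atoms)
}

# Quick structural scan so malformed records fail with a line number rather
# than an opaque parse error downstream.
validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": fewer than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": unparseable coordinates")
  }
  invisible(TRUE)
}

# Keep one record per (chain, residue number, atom name): highest occupancy,
# ties broken by file order.
resolve_altloc <- function(alt, chain, resno, elety, occ) {
  occ[is.na(occ)] <- 1
  key <- paste(chain, resno, trimws(elety))
  ord <- order(key, -occ, seq_along(key))
  first <- !duplicated(key[ord])
  sort(ord[first])
}

#' Write a molecular system as a PDB file
#'
#' @param system a [molecular_system()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_structure <- function(system, path) {
  a <- system$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$type,
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = a$serial, elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Construct a trajectory ensemble
#'
#' Couples a fixed atom set (the system) with an ordered series of coordinate
#' frames. Coordinates are stored bio3d-style as an `n_frames x (3 * n_atoms)`
#' matrix in x1,y1,z1,x2,... order.
#'
#' @param system a [molecular_system()]
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms(system)` columns
#' @param frame_times numeric vector of frame times in ns, strictly increasing
#' @return an object of class `trajectory_ensemble`
#' @export
trajectory_ensemble <- function(system, xyz, frame_times = NULL) {
  xyz <- as.matrix(xyz)
  na <- n_atoms(system)
  if (ncol(xyz) != 3L * na)
    stop("frame atom count mismatch: system has ", na, " atoms but frames have ",
         ncol(xyz) / 3, " atoms")
  if (is.null(frame_times)) frame_times <- as.numeric(seq_len(nrow(xyz)) - 1L)
  if (length(frame_times) != nrow(xyz))
    stop("frame_times length (", length(frame_times), ") != frame count (", nrow(xyz), ")")
  if (nrow(xyz) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory frames")
  structure(list(system = system, xyz = unname(xyz),
                 frame_times = as.numeric(frame_times)),
            class = "trajectory_ensemble")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory_ensemble`
#' @return integer frame count
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param traj a `trajectory_ensemble`
#' @param i frame index (1-based)
#' @return numeric matrix with columns x, y, z
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms, t = %g..%g ns\n",
              n_frames(x), n_atoms(x$system),
              x$frame_times[1], x$frame_times[length(x$frame_times)]))
  invisible(x)
}

#' Read a coordinate trajectory against a known system
#'
#' Supports multi-model PDB and CHARMM/NAMD-dialect DCD. Frame times are
#' metadata supplied here (default: frame index times `stride_ns`), never
#' inferred from DCD headers, whose time conventions vary by writer.
#'
#' @param system the [molecular_system()] the frames belong to
#' @param path trajectory file path
#' @param dialect `"multi-model-pdb"` or `"dcd"`; default guesses from the
#'   file extension (`.pdb` vs `.dcd`)
#' @param stride_ns time per frame in ns used to synthesize frame times
#' @param frame_times explicit frame times in ns, overriding `stride_ns`
#' @return a [trajectory_ensemble()]
#' @export
read_trajectory <- function(system, path,
                            dialect = c("auto", "multi-model-pdb", "dcd"),
                            stride_ns = 1.0, frame_times = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "multi-model-pdb"
  xyz <- switch(dialect,
    "multi-model-pdb" = {
      pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                              verbose = FALSE))
      unclass(pdb$xyz)
    },
    "dcd" = read_dcd_xyz(path))
  xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  na <- n_atoms(system)
  if (ncol(xyz) != 3L * na)
    stop("trajectory atom count mismatch: expected ", na, " atoms, found ",
         ncol(xyz) / 3)
  if (is.null(frame_times)) frame_times <- (seq_len(nrow(xyz)) - 1) * stride_ns
  trajectory_ensemble(system, xyz, frame_times)
}

#' Write a trajectory to disk
#'
#' @param traj a [trajectory_ensemble()]
#' @param path output path
#' @param dialect `"multi-model-pdb"` or `"dcd"`; default guesses from the
#'   extension
#' @return the path, invisibly
#' @export
write_trajectory <- function(traj, path,
                             dialect = c("auto", "multi-model-pdb", "dcd")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "multi-model-pdb"
  if (dialect == "multi-model-pdb") {
    a <- traj$system$atoms
    bio3d::write.pdb(file = path, xyz = traj$xyz, type = a$type,
                     resno = a$residue_number, resid = a$residue_name,
                     eleno = a$serial, elety = a$atom_name,
                     chain = a$chain_id, elesy = a$element)
  } else {
    write_dcd_xyz(traj$xyz, path)
  }
  invisible(path)
}

read_dcd_xyz <- function(path) {
  unclass(bio3d::read.dcd(path, verbose = FALSE))
}

# Minimal CHARMM-dialect DCD writer: 32-bit little-endian Fortran records,
# 'CORD' header with version flag 24, one title line, no unit cell. Single
# float precision (~1e-5 relative), matching the format's own precision.
write_dcd_xyz <- function(xyz, path) {
  nf <- nrow(xyz)
  natom <- ncol(xyz) / 3L
  con <- file(path, "wb")
  on.exit(close(con))
  marker <- function(n) writeBin(as.integer(n), con, size = 4, endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  marker(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4, endian = "little")
  marker(84)
  title <- sprintf("%-80s", "written by diccr")
  marker(84)
  writeBin(1L, con, size = 4, endian = "little")
  writeChar(title, con, nchars = 80, eos = NULL)
  marker(84)
  marker(4); writeBin(as.integer(natom), con, size = 4, endian = "little"); marker(4)
  xi <- seq(1, 3 * natom, by = 3)
  for (i in seq_len(nf)) {
    fr <- xyz[i, ]
    for (off in 0:2) {
      marker(4 * natom)
      writeBin(as.numeric(fr[xi + off]), con, size = 4, endian = "little")
      marker(4 * natom)
    }
  }
  invisible(path)
}
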