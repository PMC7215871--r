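#' Atom-pair distance time series
#'
#' Per-frame Euclidean distance between two atoms, e.g. a ligand carbon and
#' a side-chain atom, as used to monitor ligand translocation. Distances are
#' invariant to any global alignment, so raw and aligned trajectories give
#' identical series; the `aligned` flag exists only so pipelines can be
#' explicit about which coordinates they pass.
#'
#' @param traj a [trajectory_ensemble()]
#' @param atom_a,atom_b atom indices (from [find_atom()]) or lists
#'   `list(residue_number=, atom_name=, chain_id=)`
#' @param aligned documentation-only flag recorded in the result
#' @return data.frame (`time_ns`, `distance_A`) with attributes `atom_a`,
#'   `atom_b` describing the pair
#' @export
pair_distance_series <- function(traj, atom_a, atom_b, aligned = FALSE) {
  ia <- resolve_atom_arg(traj$system, atom_a)
  ib <- resolve_atom_arg(traj$system, atom_b)
  if (ia == ib) stop("self-pair: atom_a and atom_b resolve to the same atom")
  ca <- traj$xyz[, (3 * ia - 2):(3 * ia), drop = FALSE]
  cb <- traj$xyz[, (3 * ib - 2):(3 * ib), drop = FALSE]
  d <- sqrt(rowSums((ca - cb)^2))
  out <- data.frame(time_ns = traj$frame_times, distance_A = d)
  attr(out, "atom_a") <- atom_label(traj$system, ia)
  attr(out, "atom_b") <- atom_label(traj$system, ib)
  attr(out, "aligned") <- aligned
  out
}

resolve_atom_arg <- function(system, atom) {
  if (is.numeric(atom) && length(atom) == 1L) {
    atom <- as.integer(atom)
    if (atom < 1L || atom > n_atoms(system))
      stop("atom index ", atom, " out of bounds (1..", n_atoms(system), ")")
    return(atom)
  }
  if (is.list(atom))
    return(find_atom(system, atom$residue_number, atom$atom_name,
                     chain_id = atom$chain_id))
  stop("atom must be an index or list(residue_number=, atom_name=, chain_id=)")
}

atom_label <- function(system, i) {
  a <- system$atoms[i, ]
  sprintf("%s/%s%d/%s", a$chain_id, a$residue_name, a$residue_number, a$atom_name)
}

#' Residues within a cutoff of a query selection
#'
#' A residue enters the shell iff the minimum distance over all (query atom,
#' residue atom) pairs is less than or equal to the cutoff (inclusive
#' boundary). Residues contributing atoms to the query itself are excluded.
#'
#' @param frame n_atoms x 3 coordinate matrix of one frame (see
#'   [frame_coords()]) or a [molecular_system()] for its static coordinates
#' @param system the [molecular_system()] describing the atoms
#' @param query an [atom_selection()], e.g. the ligand atoms
#' @param universe an [atom_selection()] to search within; default all atoms
#' @param cutoff shell radius in Angstrom (default 5.0)
#' @return data.frame (`chain_id`, `residue_number`, `residue_name`,
#'   `min_distance_A`) sorted by increasing distance
#' @export
contact_shell <- function(frame, system, query, universe = NULL, cutoff = 5.0) {
  if (inherits(frame, "molecular_system")) {
    system <- frame
    frame <- coords(system)
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!length(query)) stop("empty query selection")
  if (is.null(universe)) universe <- atom_selection(seq_len(n_atoms(system)), "all")
  a <- system$atoms
  qres <- unique(paste(a$chain_id[query], a$residue_number[query]))
  ures <- paste(a$chain_id[universe], a$residue_number[universe])
  cand <- universe[!(ures %in% qres)]
  if (!length(cand))
    return(data.frame(chain_id = character(), residue_number = integer(),
                      residue_name = character(), min_distance_A = numeric()))
  qc <- frame[query, , drop = FALSE]
  uc <- frame[cand, , drop = FALSE]
  # pairwise distances query x candidate via the expanded-square identity
  d2 <- outer(rowSums(qc^2), rowSums(uc^2), "+") - 2 * tcrossprod(qc, uc)
  dmin_atom <- sqrt(pmax(apply(d2, 2, min), 0))
  key <- paste(a$chain_id[cand], a$residue_number[cand])
  dres <- tapply(dmin_atom, key, min)
  hit <- names(dres)[dres <= cutoff]
  if (!length(hit))
    return(data.frame(chain_id = character(), residue_number = integer(),
                      residue_name = character(), min_distance_A = numeric()))
  info <- do.call(rbind, lapply(hit, function(k) {
    i <- cand[match(k, key)]
    data.frame(chain_id = a$chain_id[i], residue_number = a$residue_number[i],
               residue_name = a$residue_name[i],
               min_distance_A = unname(dres[[k]]), stringsAsFactors = FALSE)
  }))
  info[order(info$min_distance_A, info$residue_number), , drop = FALSE]
}

#' Geometric hydrogen-bond network over a trajectory
#'
#' A donor/acceptor heavy-atom pair counts as hydrogen-bonded in a frame iff
#' their distance is less than or equal to `cutoff` (3.5 Angstrom by
#' convention); occupancy is the fraction of frames in which the pair is
#' bonded. The criterion is distance-only by default; an optional
#' D-H...A angle term (hydrogens located by <= 1.25 Angstrom proximity to
#' the donor in each frame) can be switched on via `angle_min`.
#'
#' @param traj a [trajectory_ensemble()]
#' @param donors,acceptors [atom_selection()]s restricted to N/O/S heavy
#'   atoms (validated; anything else errors)
#' @param cutoff heavy-atom distance criterion in Angstrom (default 3.5)
#' @param occupancy_min only pairs with at least this bonded-frame fraction
#'   are returned (default 0)
#' @param angle_min optional minimum D-H...A angle in degrees (e.g. 120);
#'   `NULL` (default) disables the angle term
#' @return data.frame (`donor`, `acceptor`, `min_distance_A`,
#'   `mean_distance_A`, `occupancy`) sorted by decreasing occupancy, ties by
#'   increasing minimum distance then labels
#' @export
hbond_network <- function(traj, donors, acceptors, cutoff = 3.5,
                          occupancy_min = 0, angle_min = NULL) {
  a <- traj$system$atoms
  check_nos <- function(sel, what) {
    bad <- setdiff(unique(a$element[sel]), c("N", "O", "S"))
    if (length(bad))
      stop(what, " selection contains non-N/O/S atoms (elements: ",
           paste(bad, collapse = ", "), ")")
  }
  check_nos(donors, "donor"); check_nos(acceptors, "acceptor")
  nf <- n_frames(traj)
  hyd <- which(a$element %in% c("H", "D"))

  pairs <- expand.grid(d = as.integer(donors), ac = as.integer(acceptors))
  pairs <- pairs[pairs$d != pairs$ac, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(donor = character(), acceptor = character(),
                      min_distance_A = numeric(), mean_distance_A = numeric(),
                      occupancy = numeric()))
  bonded <- matrix(FALSE, nf, nrow(pairs))
  dists <- matrix(NA_real_, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    dv <- sqrt(rowSums((fr[pairs$d, , drop = FALSE] -
                        fr[pairs$ac, , drop = FALSE])^2))
    dists[f, ] <- dv
    ok <- dv <= cutoff
    if (!is.null(angle_min) && any(ok)) {
      for (p in which(ok)) {
        hs <- donor_hydrogens(fr, pairs$d[p], hyd)
        ok[p] <- length(hs) > 0 &&
          any(vapply(hs, function(h)
            dha_angle(fr[pairs$d[p], ], fr[h, ], fr[pairs$ac[p], ]) >= angle_min,
            logical(1)))
      }
    }
    bonded[f, ] <- ok
  }
  occ <- colMeans(bonded)
  keep <- which(occ >= occupancy_min & occ > 0)
  if (!length(keep))
    return(data.frame(donor = character(), acceptor = character(),
                      min_distance_A = numeric(), mean_distance_A = numeric(),
                      occupancy = numeric()))
  out <- data.frame(
    donor = vapply(pairs$d[keep], function(i) atom_label(traj$system, i), ""),
    acceptor = vapply(pairs$ac[keep], function(i) atom_label(traj$system, i), ""),
    min_distance_A = vapply(keep, function(p) min(dists[, p]), 0),
    mean_distance_A = vapply(keep, function(p) mean(dists[bonded[, p], p]), 0),
    occupancy = occ[keep], stringsAsFactors = FALSE)
  out[order(-out$occupancy, out$min_distance_A, out$donor, out$acceptor), ,
      drop = FALSE]
}

donor_hydrogens <- function(fr, donor, hyd) {
  if (!length(hyd)) return(integer())
  d <- sqrt(rowSums((fr[hyd, , drop = FALSE] -
                     matrix(fr[donor, ], length(hyd), 3, byrow = TRUE))^2))
  hyd[d <= 1.25]
}

dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}
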