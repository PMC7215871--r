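#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the cross-covariance matrix with the
#' usual determinant correction that excludes reflections.
#'
#' @param mobile n x 3 coordinate matrix to be moved
#' @param reference n x 3 coordinate matrix to superpose onto
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3,
#'   Angstrom) and `rmsd` (Angstrom). The transform maps a coordinate row
#'   `v` to `v %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be n x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  if (nrow(mobile) < 3L)
    stop("superposition needs at least 3 points, got ", nrow(mobile))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  # rank < 2 (collinear/degenerate point sets) leaves the rotation underdetermined
  if (sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8) < 2L &&
      (sum(P^2) > 0 && sum(Q^2) > 0))
    stop("degenerate (rank-deficient) covariance: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R,
       translation = as.numeric(cr - as.numeric(R %*% cm)),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform list with `rotation` and `translation` as returned by
#'   [kabsch_superpose()]
#' @param x n x 3 coordinate matrix
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(transform, x) {
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' Plain unweighted RMSD with no fitting; superpose first if alignment is
#' wanted.
#'
#' @param a,b n x 3 coordinate matrices
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3L, ncol(b) == 3L)
  sqrt(mean(rowSums((a - b)^2)))
}

resolve_reference <- function(traj, reference) {
  if (is.character(reference) && length(reference) == 1L &&
      reference == "first-frame")
    return(frame_coords(traj, 1L))
  ref <- as.matrix(reference)
  if (ncol(ref) != 3L || nrow(ref) != n_atoms(traj$system))
    stop("reference must be 'first-frame' or a full-system n_atoms x 3 matrix")
  ref
}

#' Globally align every frame of a trajectory
#'
#' Each frame is superposed onto the reference using only the fit selection
#' (typically the protein backbone); the resulting rigid transform is applied
#' to every atom of the frame, so ligands and solvent ride along with the
#' protein fit.
#'
#' @param traj a [trajectory_ensemble()]
#' @param fit_selection an [atom_selection()] to fit on; default all protein
#'   backbone atoms
#' @param reference `"first-frame"` or a full-system n x 3 coordinate matrix
#' @return a new, aligned [trajectory_ensemble()]
#' @export
align_trajectory <- function(traj, fit_selection = NULL,
                             reference = "first-frame") {
  if (is.null(fit_selection))
    fit_selection <- resolve_selection(traj$system, NULL, "backbone")
  ref <- resolve_reference(traj, reference)
  ref_fit <- ref[fit_selection, , drop = FALSE]
  out <- traj$xyz
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, i)
    tr <- tryCatch(
      kabsch_superpose(fr[fit_selection, , drop = FALSE], ref_fit),
      error = function(e) stop("alignment failed at frame ", i, ": ",
                               conditionMessage(e)))
    out[i, ] <- as.vector(t(apply_transform(tr, fr)))
  }
  trajectory_ensemble(traj$system, out, traj$frame_times)
}

#' Per-domain RMSD time series
#'
#' Frames are first globally aligned on `fit_selection` (unless
#' `fit = FALSE`), then for each domain the RMSD to the reference coordinates
#' is computed without any per-domain refitting, so genuine inter-domain
#' motion is retained in the series.
#'
#' @param traj a [trajectory_ensemble()] with at least 2 frames
#' @param domains named list of [domain_definition()] or [atom_selection()]
#'   objects
#' @param fit_selection selection used for the global alignment; default all
#'   protein backbone atoms
#' @param reference `"first-frame"` or a full-system n x 3 matrix
#' @param atom_filter filter applied when resolving domain definitions
#' @param fit set `FALSE` to skip the global alignment (frames used as-is)
#' @return data.frame with column `time_ns` and one RMSD column (Angstrom)
#'   per domain
#' @export
rmsd_series <- function(traj, domains, fit_selection = NULL,
                        reference = "first-frame", atom_filter = "backbone",
                        fit = TRUE) {
  if (n_frames(traj) < 2L) stop("rmsd_series needs at least 2 frames")
  sels <- lapply(seq_along(domains), function(k) {
    d <- domains[[k]]
    if (inherits(d, "atom_selection")) d
    else resolve_selection(traj$system, d, atom_filter)
  })
  labels <- names(domains)
  if (is.null(labels))
    labels <- vapply(domains, function(d)
      if (inherits(d, "domain_definition")) d$name else "selection", "")
  ref <- resolve_reference(traj, reference)
  if (fit) traj <- align_trajectory(traj, fit_selection, reference = ref)
  out <- matrix(0, n_frames(traj), length(sels))
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, i)
    for (k in seq_along(sels)) {
      s <- sels[[k]]
      out[i, k] <- rmsd(fr[s, , drop = FALSE], ref[s, , drop = FALSE])
    }
  }
  df <- data.frame(time_ns = traj$frame_times)
  df[labels] <- as.data.frame(out)
  df
}

#' Net displacement of a selection's centroid
#'
#' Euclidean distance between the unweighted centroid of the selection in
#' the first and last frames. Align the trajectory first if the displacement
#' should be measured in the protein frame of reference.
#'
#' @param traj a [trajectory_ensemble()] with at least 2 frames
#' @param selection an [atom_selection()]
#' @return displacement in Angstrom
#' @export
net_displacement <- function(traj, selection) {
  if (n_frames(traj) < 2L) stop("net_displacement needs at least 2 frames")
  if (!length(selection)) stop("empty selection")
  first <- colMeans(frame_coords(traj, 1L)[selection, , drop = FALSE])
  last <- colMeans(frame_coords(traj, n_frames(traj))[selection, , drop = FALSE])
  sqrt(sum((last - first)^2))
}
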