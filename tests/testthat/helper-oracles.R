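# Independent oracles used across the suite. These deliberately share no
# code with the package: literal loop transcriptions and grid searches.

# Literal transcription of the distance-correlation statistic: raw
# inter-frame distances, double centering by explicit row/column/grand
# means, V-statistic double sums.
naive_dicc <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  dm <- function(X) {
    D <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    D
  }
  ctr <- function(D) {
    H <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      H[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D)
    H
  }
  nu <- function(HA, HB) {
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + HA[i, j] * HB[i, j]
    s / n^2
  }
  HA <- ctr(dm(A)); HB <- ctr(dm(B))
  vab <- nu(HA, HB); vaa <- nu(HA, HA); vbb <- nu(HB, HB)
  list(dcov = vab, dvar_a = vaa, dvar_b = vbb,
       dicc = if (vaa <= 0 || vbb <= 0) NA_real_
              else sqrt(max(vab, 0) / sqrt(vaa * vbb)))
}

# Euler-angle rotation matrix (z-y-z convention)
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# Minimum RMSD over proper rotations + translations via a coarse Euler grid
# refined with Nelder-Mead; independent of the SVD route.
grid_search_rmsd <- function(mobile, reference, grid_deg = 15) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step <- grid_deg * pi / 180
  best <- NULL; best_val <- Inf
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step / 2, by = step)) {
        v <- obj(c(a, b, g))
        if (v < best_val) { best_val <- v; best <- c(a, b, g) }
      }
  ref <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  ref$value
}

# O(N^2) brute-force contact scan: per-residue minimum over all
# (query atom, universe atom) pairs, inclusive cutoff, query residues out.
brute_contact_shell <- function(frame, system, query, universe, cutoff) {
  a <- system$atoms
  qres <- unique(paste(a$chain_id[query], a$residue_number[query]))
  res_min <- list()
  for (u in universe) {
    key <- paste(a$chain_id[u], a$residue_number[u])
    if (key %in% qres) next
    for (q in query) {
      d <- sqrt(sum((frame[q, ] - frame[u, ])^2))
      if (is.null(res_min[[key]]) || d < res_min[[key]]) res_min[[key]] <- d
    }
  }
  keys <- names(res_min)[unlist(res_min) <= cutoff]
  data.frame(key = keys, min_distance_A = unlist(res_min[keys]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# random proper rotation via QR with positive-diagonal correction
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid motion to every frame of a trajectory matrix (bio3d layout)
transform_xyz <- function(xyz, R, t) {
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    fr <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    out[i, ] <- as.vector(t(sweep(fr %*% t(R), 2, t, "+")))
  }
  out
}

# small hand-built system: one chain, residues with given numbers, one CA
# atom each unless atom data supplied
toy_system <- function(resno, coords, atom_name = "CA", residue_name = "ALA",
                       element = "C", type = "ATOM") {
  n <- length(resno)
  molecular_system(data.frame(
    serial = seq_len(n), type = rep_len(type, n),
    atom_name = rep_len(atom_name, n),
    residue_name = rep_len(residue_name, n),
    residue_number = resno, chain_id = "A",
    element = rep_len(element, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# trajectory from a list of n x 3 frame matrices
toy_trajectory <- function(system, frames, times = NULL) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  trajectory_ensemble(system, xyz, times)
}

toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.729   6.768  -4.123  1.00  0.00           C",
  "END")

altloc_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
  "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
  "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
  "END")

# two-oxygen system at a given separation, constant over 3 frames
hbond_toy_boundary <- function(sep) {
  sys <- toy_system(resno = c(1, 2),
                    coords = rbind(c(0, 0, 0), c(sep, 0, 0)),
                    atom_name = c("OG", "OH"), residue_name = c("SER", "TYR"),
                    element = "O")
  toy_trajectory(sys, rep(list(cbind(c(0, sep), 0, 0)), 3))
}
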