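#' Inter-frame Euclidean distance matrix of a position series
#'
#' A position series is one configuration vector per trajectory frame (for a
#' domain: the concatenated coordinates of its atoms). Entry (i, j) is the
#' Euclidean distance between the configurations at frames i and j.
#'
#' @param x numeric matrix, one row per frame (n frames x d dimensions)
#' @return symmetric n x n matrix with zero diagonal
#' @export
frame_distance_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("position series needs at least 2 frames")
  as.matrix(stats::dist(x))
}

#' Double-center a square matrix
#'
#' Subtracts row and column means and adds back the grand mean, producing
#' the hat-matrix whose rows and columns sum to zero — the centering step of
#' the distance-covariance statistic.
#'
#' @param D square numeric matrix
#' @return matrix of the same shape with zero row and column sums
#' @export
double_center <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("double_center requires a square matrix")
  rm <- rowMeans(D); cm <- colMeans(D); gm <- mean(D)
  D - outer(rm, rep(1, ncol(D))) - outer(rep(1, nrow(D)), cm) + gm
}

centered_frame_distances <- function(x) double_center(frame_distance_matrix(x))

#' Distance covariance between two position series
#'
#' The squared sample distance covariance nu(A, B) = (1/n^2) * sum_ij
#' a_ij * b_ij over the double-centered inter-frame distance matrices of the
#' two series (Szekely-Rizzo V-statistic). nu(A, A) >= 0 up to rounding.
#'
#' @param a,b numeric matrices, one row per frame; equal frame counts
#' @return scalar distance covariance
#' @export
distance_covariance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("frame counts differ: ", nrow(a), " vs ", nrow(b))
  mean(centered_frame_distances(a) * centered_frame_distances(b))
}

dcov_from_centered <- function(ahat, bhat) mean(ahat * bhat)

#' Distance correlation coefficient (DiCC) between two position series
#'
#' DiCC = sqrt(nu(A,B) / sqrt(nu(A,A) * nu(B,B))), the sample distance
#' correlation of Szekely and Rizzo: 1 for fully dependent motion, near 0
#' for independent motion. Being built on inter-frame distances it is
#' invariant to rigid rotation, translation, reflection, and positive
#' scaling applied uniformly to either series. Negative covariances arising
#' from floating-point cancellation are clamped at 0. If either series has
#' zero distance variance (all frames identical) the statistic is undefined
#' and `NA` is returned, never 0.
#'
#' @param a,b numeric matrices, one row per frame
#' @param squared return the squared statistic R^2 instead of R
#' @return scalar in `[0, 1]`, or `NA` when undefined
#' @export
distance_correlation <- function(a, b, squared = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("frame counts differ: ", nrow(a), " vs ", nrow(b))
  ahat <- centered_frame_distances(a)
  bhat <- centered_frame_distances(b)
  dicc_from_centered(ahat, bhat, squared = squared)
}

dicc_from_centered <- function(ahat, bhat, squared = FALSE) {
  vaa <- dcov_from_centered(ahat, ahat)
  vbb <- dcov_from_centered(bhat, bhat)
  if (vaa <= 0 || vbb <= 0) return(NA_real_)
  vab <- max(dcov_from_centered(ahat, bhat), 0)
  r2 <- vab / sqrt(vaa * vbb)
  r2 <- min(r2, 1)
  if (squared) r2 else sqrt(r2)
}

#' Domain-by-domain DiCC matrix of an aligned trajectory
#'
#' For each domain a position series is formed from its filtered atoms and
#' the DiCC is computed for every pair of domains. Two series constructions
#' are available:
#' \describe{
#'   \item{`domain-vector`}{one concatenated coordinate vector per frame
#'     (dimension 3 x atoms in the domain); the default.}
#'   \item{`atom-pair-mean`}{the DiCC of every (atom in A, atom in B) pair of
#'     3-D position series, arithmetically averaged; the per-atom reading
#'     used by some trajectory distance-correlation implementations.}
#' }
#' The trajectory is expected to be aligned already (see
#' [align_trajectory()]): rigid global motion otherwise couples all domains.
#'
#' @param traj an aligned [trajectory_ensemble()] with >= 2 frames
#' @param domains named list of [domain_definition()] objects
#' @param mode `"domain-vector"` or `"atom-pair-mean"`
#' @param atom_filter atom filter per domain; default `"backbone"` (use
#'   `"CA"` via `c("CA")` for a faster atom-pair-mean run)
#' @param squared report squared distance correlation instead of R
#' @param stride keep every `stride`-th frame (default 1 = all frames)
#' @return a `dicc_matrix`: symmetric numeric matrix with domain labels,
#'   unit diagonal (NA where a domain never moves), and attributes `mode`,
#'   `atom_filter`, `n_frames`, `squared`
#' @export
domain_dicc_matrix <- function(traj, domains, mode = c("domain-vector", "atom-pair-mean"),
                               atom_filter = "backbone", squared = FALSE,
                               stride = 1L) {
  mode <- match.arg(mode)
  if (n_frames(traj) < 2L) stop("DiCC needs at least 2 frames")
  labels <- names(domains)
  if (is.null(labels)) labels <- vapply(domains, function(d) d$name, "")
  sels <- lapply(domains, function(d) resolve_selection(traj$system, d, atom_filter))
  keep_frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (length(keep_frames) < 2L) stop("stride leaves fewer than 2 frames")

  k <- length(sels)
  M <- matrix(NA_real_, k, k, dimnames = list(labels, labels))

  xyz_cols <- function(sel) as.vector(rbind(3L * sel - 2L, 3L * sel - 1L, 3L * sel))

  if (mode == "domain-vector") {
    ahat <- lapply(sels, function(sel)
      centered_frame_distances(traj$xyz[keep_frames, xyz_cols(sel), drop = FALSE]))
    for (i in seq_len(k)) for (j in i:k) {
      M[i, j] <- M[j, i] <- dicc_from_centered(ahat[[i]], ahat[[j]], squared = squared)
    }
  } else {
    # per-atom centered distance matrices, computed once per domain
    per_atom <- lapply(sels, function(sel)
      lapply(sel, function(ai)
        centered_frame_distances(
          traj$xyz[keep_frames, (3L * ai - 2L):(3L * ai), drop = FALSE])))
    for (i in seq_len(k)) for (j in i:k) {
      vals <- numeric(0)
      for (ha in per_atom[[i]]) for (hb in per_atom[[j]])
        vals <- c(vals, dicc_from_centered(ha, hb, squared = squared))
      M[i, j] <- M[j, i] <- mean(vals, na.rm = TRUE)
    }
    # diagonal is the self-DiCC of the domain series, not a pair average
    for (i in seq_len(k)) {
      hi <- centered_frame_distances(
        traj$xyz[keep_frames, xyz_cols(sels[[i]]), drop = FALSE])
      M[i, i] <- dicc_from_centered(hi, hi, squared = squared)
    }
  }
  dicc_matrix(M, mode = mode, atom_filter = atom_filter,
              n_frames = length(keep_frames), squared = squared)
}

#' Construct / validate a DiCC matrix object
#'
#' @param values symmetric numeric matrix with domain labels as dimnames;
#'   entries in `[0, 1]` or `NA` for undefined cells
#' @param mode,atom_filter,n_frames,squared provenance metadata
#' @return object of class `dicc_matrix`
#' @export
dicc_matrix <- function(values, mode = NA_character_, atom_filter = NA_character_,
                        n_frames = NA_integer_, squared = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("DiCC matrix must be square")
  if (is.null(rownames(values))) stop("DiCC matrix needs domain labels")
  ok <- is.na(values) | (values >= -1e-12 & values <= 1 + 1e-12)
  if (!all(ok)) stop("DiCC entries must lie in [0, 1]")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9)
    stop("DiCC matrix must be symmetric")
  structure(values, class = c("dicc_matrix", "matrix"),
            mode_label = mode, atom_filter = atom_filter,
            n_frames = n_frames, squared = squared)
}

#' @export
print.dicc_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("DiCC matrix (%d domains%s)\n", nrow(x),
              if (is.na(attr(x, "n_frames"))) ""
              else sprintf(", %d frames, mode %s", attr(x, "n_frames"),
                           attr(x, "mode_label"))))
  print(round(bare_matrix(x), digits))
  invisible(x)
}

bare_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' Cellwise absolute difference of two DiCC matrices
#'
#' Used to localize changes in inter-domain coupling between two conditions
#' (e.g. wild type versus mutant): Delta = |DiCC_1 - DiCC_2|.
#'
#' @param m1,m2 `dicc_matrix` objects with identical domain labels and order
#' @return a `delta_dicc_matrix` (non-negative, zero diagonal, symmetric)
#'   with attribute `argmax`, a list naming the largest off-diagonal cell
#' @export
delta_dicc <- function(m1, m2) {
  if (!identical(rownames(m1), rownames(m2)))
    stop("domain labels differ between matrices: ",
         paste(rownames(m1), collapse = ","), " vs ",
         paste(rownames(m2), collapse = ","))
  d <- abs(unclass(m1) - unclass(m2))
  off <- d; diag(off) <- NA
  am <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)
  # ties broken lexicographically by (row label, col label)
  am <- am[order(rownames(d)[am[, 1]], colnames(d)[am[, 2]]), , drop = FALSE]
  argmax <- list(domain_a = rownames(d)[am[1, 1]],
                 domain_b = colnames(d)[am[1, 2]],
                 value = off[am[1, 1], am[1, 2]])
  structure(d, class = c("delta_dicc_matrix", "matrix"), argmax = argmax)
}

#' @export
print.delta_dicc_matrix <- function(x, digits = 3, ...) {
  am <- attr(x, "argmax")
  cat(sprintf("DeltaDiCC matrix; largest off-diagonal change %s-%s = %.3f\n",
              am$domain_a, am$domain_b, am$value))
  print(round(bare_matrix(x), digits))
  invisible(x)
}

#' Rank off-diagonal cells of a Delta-DiCC matrix
#'
#' @param d a `delta_dicc_matrix`
#' @return data.frame (domain_a, domain_b, delta) sorted by decreasing
#'   `delta`, ties broken by label order; one row per unordered pair
#' @export
rank_delta_cells <- function(d) {
  labs <- rownames(d)
  k <- length(labs)
  rows <- do.call(rbind, lapply(seq_len(k - 1), function(i)
    data.frame(domain_a = labs[i], domain_b = labs[(i + 1):k],
               delta = unclass(d)[i, (i + 1):k], stringsAsFactors = FALSE)))
  rows <- rows[order(-rows$delta, rows$domain_a, rows$domain_b), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Write a DiCC (or Delta-DiCC) matrix as CSV
#'
#' Values are rounded to 3 decimals to match the conventional presentation
#' of correlation tables; use [write_dicc_json()] for full precision.
#' Undefined cells are written as empty fields.
#'
#' @param m matrix with domain labels
#' @param path output CSV path
#' @param digits decimal places (default 3)
#' @return the path, invisibly
#' @export
write_dicc_csv <- function(m, path, digits = 3) {
  vals <- round(bare_matrix(m), digits)
  txt <- matrix(format(vals, nsmall = digits, trim = TRUE),
                nrow(vals), ncol(vals), dimnames = dimnames(vals))
  txt[is.na(vals)] <- ""
  df <- data.frame(domain = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a DiCC matrix (full precision) as JSON
#'
#' @param m a `dicc_matrix` or `delta_dicc_matrix`
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_dicc_json <- function(m, path) {
  payload <- list(labels = rownames(m), values = unclass(m),
                  mode = attr(m, "mode_label"), atom_filter = attr(m, "atom_filter"),
                  n_frames = attr(m, "n_frames"), squared = attr(m, "squared"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a DiCC matrix from CSV
#'
#' Expects the layout written by [write_dicc_csv()]: a `domain` label column
#' followed by one column per domain. Empty fields become `NA`.
#'
#' @param path CSV path
#' @return a `dicc_matrix`
#' @export
read_dicc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(labs, colnames(df)[-1])
  if (!identical(labs, colnames(vals)))
    stop("row and column labels disagree in ", path)
  dicc_matrix(vals)
}
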