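make_pair_system <- function(sep = 7.35) {
  toy_system(resno = c(610, 691),
             coords = rbind(c(0, 0, 0), c(0, 0, sep)),
             atom_name = c("OG", "CG"), residue_name = c("GLU", "PRO"),
             element = c("O", "C"))
}

test_that("a fixed atom pair gives a constant distance series", {
  sys <- make_pair_system(7.35)
  traj <- toy_trajectory(sys, rep(list(coords(sys)), 6))
  s <- pair_distance_series(traj,
                            list(residue_number = 610, atom_name = "OG"),
                            list(residue_number = 691, atom_name = "CG"))
  expect_equal(s$distance_A, rep(7.35, 6), tolerance = 1e-12)
  s_rev <- pair_distance_series(traj,
                                list(residue_number = 691, atom_name = "CG"),
                                list(residue_number = 610, atom_name = "OG"))
  expect_identical(s$distance_A, s_rev$distance_A)
})

test_that("self pairs are rejected and unresolvable atoms list near-miss names", {
  sys <- make_pair_system()
  traj <- toy_trajectory(sys, rep(list(coords(sys)), 2))
  expect_error(pair_distance_series(traj, 1, 1), "self-pair")
  expect_error(pair_distance_series(traj,
                 list(residue_number = 610, atom_name = "OGX"),
                 list(residue_number = 691, atom_name = "CG")),
               "atoms present: OG")
})

test_that("a drifting ligand's distance series matches the per-frame norm oracle", {
  spec <- synthetic_spec(domain_sizes = c(5, 5), seed = 30, n_frames = 20)
  sys <- build_synthetic_system(spec)
  traj <- simulate_trajectory(sys, spec)
  lig_res <- sys$atoms$residue_number[sys$atoms$atom_name == "C25"]
  s <- pair_distance_series(traj,
                            list(residue_number = lig_res, atom_name = "C25"),
                            list(residue_number = 1, atom_name = "CA"))
  ia <- find_atom(sys, lig_res, "C25"); ib <- find_atom(sys, 1, "CA")
  for (i in seq_len(20))
    expect_equal(s$distance_A[i],
                 sqrt(sum((frame_coords(traj, i)[ia, ] -
                           frame_coords(traj, i)[ib, ])^2)),
                 tolerance = 1e-12)
})

planted_shell_system <- function() {
  # query residue 999 at origin; three residues at min distances 2.9/4.9/5.1
  toy_system(resno = c(999, 1, 2, 3),
             coords = rbind(c(0, 0, 0), c(2.9, 0, 0), c(0, 4.9, 0),
                            c(0, 0, 5.1)),
             atom_name = c("C25", "CB", "CB", "CB"),
             residue_name = c("LIG", "ALA", "ALA", "ALA"),
             element = "C", type = c("HETATM", "ATOM", "ATOM", "ATOM"))
}

test_that("contact shells use an inclusive cutoff and exclude the query residue", {
  sys <- planted_shell_system()
  q <- atom_selection(1L, "ligand")
  shell <- contact_shell(coords(sys), sys, q, cutoff = 5.0)
  expect_equal(sort(shell$residue_number), c(1, 2))
  # boundary: exactly at the cutoff is included
  at_cut <- contact_shell(coords(sys), sys, q, cutoff = 5.1)
  expect_true(3 %in% at_cut$residue_number)
  expect_false(999 %in% at_cut$residue_number)
  expect_error(contact_shell(coords(sys), sys, atom_selection(integer(), "")),
               "empty query")
  expect_error(contact_shell(coords(sys), sys, q, cutoff = -1), "positive")
})

test_that("contact shells equal an O(N^2) brute-force scan on a random frame", {
  set.seed(31)
  n_res <- 125L
  atoms <- data.frame(
    serial = 1:(n_res * 4), type = "ATOM",
    atom_name = rep(c("N", "CA", "C", "O"), n_res),
    residue_name = "ALA",
    residue_number = rep(seq_len(n_res), each = 4), chain_id = "A",
    element = rep(c("N", "C", "C", "O"), n_res),
    x = rnorm(n_res * 4, sd = 12), y = rnorm(n_res * 4, sd = 12),
    z = rnorm(n_res * 4, sd = 12), stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  q <- resolve_selection(sys, domain_definition("probe", list(c(1, 2))), "all")
  u <- atom_selection(seq_len(n_atoms(sys)), "all")
  for (cutoff in c(3.0, 5.0)) {
    fast <- contact_shell(coords(sys), sys, q, u, cutoff = cutoff)
    brute <- brute_contact_shell(coords(sys), sys, as.integer(q),
                                 as.integer(u), cutoff)
    expect_setequal(paste("A", fast$residue_number), brute$key)
    m <- match(paste("A", fast$residue_number), brute$key)
    expect_equal(fast$min_distance_A, brute$min_distance_A[m],
                 tolerance = 1e-12)
  }
})

test_that("contact shells are invariant under a global rigid transform", {
  sys <- planted_shell_system()
  q <- atom_selection(1L, "ligand")
  base <- contact_shell(coords(sys), sys, q, cutoff = 5.0)
  set.seed(32)
  moved <- sweep(coords(sys) %*% t(random_rotation()), 2, c(10, -3, 2), "+")
  after <- contact_shell(moved, sys, q, cutoff = 5.0)
  expect_equal(base, after, tolerance = 1e-9)
})

hbond_toy <- function(d_oo, n_frames = 4) {
  sys <- toy_system(resno = c(1, 2),
                    coords = rbind(c(0, 0, 0), c(d_oo, 0, 0)),
                    atom_name = c("OG", "OH"), residue_name = c("SER", "TYR"),
                    element = "O")
  toy_trajectory(sys, rep(list(coords(sys)), n_frames))
}

test_that("persistent close donor-acceptor pairs get occupancy 1; far pairs are excluded", {
  traj <- hbond_toy(2.8)
  all_sel <- atom_selection(1:2, "all")
  hb <- hbond_network(traj, all_sel, all_sel)
  expect_equal(nrow(hb), 2L)  # both orderings of the one pair
  expect_equal(hb$occupancy, c(1, 1))
  expect_equal(hb$min_distance_A, c(2.8, 2.8), tolerance = 1e-12)

  far <- hbond_network(hbond_toy(3.6), all_sel, all_sel)
  expect_equal(nrow(far), 0L)
  # boundary: exactly 3.5 is bonded (inclusive criterion)
  at <- hbond_network(hbond_toy(3.5), all_sel, all_sel)
  expect_equal(at$occupancy, c(1, 1))
})

test_that("occupancy counts bonded frames exactly (73/100 planted)", {
  sys <- toy_system(resno = c(1, 2),
                    coords = rbind(c(0, 0, 0), c(2.8, 0, 0)),
                    atom_name = c("OG", "OH"), residue_name = c("SER", "TYR"),
                    element = "O")
  frames <- lapply(1:100, function(i) {
    f <- coords(sys)
    if (i > 73) f[2, 1] <- 6.0  # break the bond in the last 27 frames
    f
  })
  traj <- toy_trajectory(sys, frames)
  hb <- hbond_network(traj, atom_selection(1L, "d"), atom_selection(2L, "a"))
  expect_equal(hb$occupancy, 0.73)
  expect_equal(hb$min_distance_A, 2.8, tolerance = 1e-12)
  # occupancy_min filters
  expect_equal(nrow(hbond_network(traj, atom_selection(1L, "d"),
                                  atom_selection(2L, "a"),
                                  occupancy_min = 0.8)), 0L)
})

test_that("non-N/O/S atoms in donor or acceptor selections are rejected", {
  sys <- toy_system(resno = c(1, 2),
                    coords = rbind(c(0, 0, 0), c(3, 0, 0)),
                    atom_name = c("CA", "OG"), residue_name = c("ALA", "SER"),
                    element = c("C", "O"))
  traj <- toy_trajectory(sys, list(coords(sys), coords(sys)))
  expect_error(hbond_network(traj, atom_selection(1L, "d"),
                             atom_selection(2L, "a")), "non-N/O/S")
})

test_that("records sort by occupancy descending and distances match a naive scan", {
  sys <- toy_system(resno = 1:3,
                    coords = rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 3.2, 0)),
                    atom_name = c("OG", "OH", "ND1"),
                    residue_name = c("SER", "TYR", "HIS"),
                    element = c("O", "O", "N"))
  frames <- lapply(1:10, function(i) {
    f <- coords(sys)
    if (i > 4) f[3, 2] <- 8  # residue 3 bonded only in frames 1..4
    f
  })
  traj <- toy_trajectory(sys, frames)
  hb <- hbond_network(traj, atom_selection(1L, "d"), atom_selection(2:3, "a"))
  expect_equal(hb$occupancy, c(1.0, 0.4))
  expect_false(is.unsorted(rev(hb$occupancy)))
  for (r in seq_len(nrow(hb))) {
    dmin <- Inf
    for (i in 1:10) {
      fr <- frame_coords(traj, i)
      j <- if (r == 1) 2L else 3L
      dmin <- min(dmin, sqrt(sum((fr[1, ] - fr[j, ])^2)))
    }
    expect_equal(hb$min_distance_A[r], dmin, tolerance = 1e-12)
  }
})

test_that("the optional D-H...A angle criterion vetoes bent geometries", {
  # donor O with H pointing at the acceptor (linear, ~180 deg) vs away
  sys <- molecular_system(data.frame(
    serial = 1:3, type = "ATOM",
    atom_name = c("OG", "HG", "OH"),
    residue_name = c("SER", "SER", "TYR"),
    residue_number = c(1L, 1L, 2L), chain_id = "A",
    element = c("O", "H", "O"),
    x = c(0, 0.95, 2.9), y = 0, z = 0, stringsAsFactors = FALSE))
  traj <- toy_trajectory(sys, rep(list(coords(sys)), 3))
  hb <- hbond_network(traj, atom_selection(1L, "d"), atom_selection(3L, "a"),
                      angle_min = 120)
  expect_equal(hb$occupancy, 1)

  bent <- sys
  bent$atoms$x[2] <- -0.95  # H points away: D-H...A angle ~0
  traj2 <- toy_trajectory(bent, rep(list(coords(bent)), 3))
  hb2 <- hbond_network(traj2, atom_selection(1L, "d"), atom_selection(3L, "a"),
                       angle_min = 120)
  expect_equal(nrow(hb2), 0L)
})
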