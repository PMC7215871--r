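test_that("superposing a set onto itself gives the identity and zero RMSD", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("pure rigid motions are fully recovered (rmsd 0, proper rotation)", {
  set.seed(2)
  x <- matrix(rnorm(24), 8, 3)
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(x %*% t(R90), 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(moved, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  expect_lt(max(abs(apply_transform(fit, moved) - x)), 1e-9)

  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    fit <- kabsch_superpose(sweep(x %*% t(R), 2, t, "+"), x)
    expect_lt(fit$rmsd, 1e-6)
  }
})

test_that("the fitted RMSD matches a rotation-grid-search oracle", {
  set.seed(3)
  for (i in 1:4) {
    mobile <- matrix(rnorm(12), 4, 3)
    reference <- mobile
    reference[1, ] <- reference[1, ] + rnorm(3, sd = 0.8)
    fit <- kabsch_superpose(mobile, reference)
    expect_equal(fit$rmsd, grid_search_rmsd(mobile, reference),
                 tolerance = 1e-3)
  }
})

test_that("fitted RMSD is symmetric and invariant to rigid motion of the mobile set", {
  set.seed(4)
  a <- matrix(rnorm(18), 6, 3)
  b <- a + matrix(rnorm(18, sd = 0.5), 6, 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  base <- kabsch_superpose(a, b)$rmsd
  for (i in 1:5) {
    moved <- sweep(a %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+")
    expect_equal(kabsch_superpose(moved, b)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("aligning a rigid tumble collapses every frame onto the reference", {
  spec <- synthetic_spec(domain_sizes = c(6, 6), com_sigma = 0,
                         jitter_sigma = 0, ligand = NULL, seed = 5,
                         n_frames = 4)
  sys <- build_synthetic_system(spec)
  base <- coords(sys)
  set.seed(6)
  frames <- lapply(1:4, function(i)
    if (i == 1) base else sweep(base %*% t(random_rotation()), 2,
                                rnorm(3, sd = 8), "+"))
  traj <- toy_trajectory(sys, frames)
  aligned <- align_trajectory(traj)
  for (i in 1:4)
    expect_lt(max(abs(frame_coords(aligned, i) - base)), 1e-6)
  # idempotence on already-aligned data
  again <- align_trajectory(aligned)
  expect_lt(max(abs(again$xyz - aligned$xyz)), 1e-6)
})

test_that("ligand atoms receive exactly the frame transform of the protein fit", {
  spec <- synthetic_spec(domain_sizes = c(6, 6), seed = 7, n_frames = 5)
  sys <- build_synthetic_system(spec)
  traj <- simulate_trajectory(sys, spec)
  set.seed(8)
  R <- random_rotation(); t <- c(3, -4, 7)
  tumbled <- trajectory_ensemble(sys, transform_xyz(traj$xyz, R, t),
                                 traj$frame_times)
  bb <- resolve_selection(sys, NULL, "backbone")
  aligned <- align_trajectory(tumbled, bb, reference = frame_coords(traj, 1))
  lig <- which(sys$atoms$residue_name == "LIG")
  for (i in 1:5) {
    fit <- kabsch_superpose(frame_coords(tumbled, i)[bb, ],
                            frame_coords(traj, 1)[bb, ])
    expect_equal(frame_coords(aligned, i)[lig, , drop = FALSE],
                 apply_transform(fit, frame_coords(tumbled, i)[lig, , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a static trajectory yields an all-zero RMSD series", {
  sys <- toy_system(1:12, matrix(rnorm(36), 12, 3), atom_name = "CA")
  traj <- toy_trajectory(sys, rep(list(coords(sys)), 4))
  doms <- list(A = domain_definition("A", list(c(1, 6))),
               B = domain_definition("B", list(c(7, 12))))
  rs <- rmsd_series(traj, doms, atom_filter = "all")
  expect_equal(unname(as.matrix(rs[, c("A", "B")])), matrix(0, 4, 2),
               tolerance = 1e-9)
  expect_equal(rs$time_ns, 0:3)
})

test_that("a uniform domain displacement of d gives RMSD exactly d without refit", {
  sys <- toy_system(1:12, matrix(rnorm(36), 12, 3), atom_name = "CA")
  base <- coords(sys)
  d <- 2.5
  shifted <- base
  shifted[7:12, 3] <- shifted[7:12, 3] + d
  traj <- toy_trajectory(sys, list(base, shifted, shifted))
  doms <- list(A = domain_definition("A", list(c(1, 6))),
               B = domain_definition("B", list(c(7, 12))))
  rs <- rmsd_series(traj, doms, atom_filter = "all", fit = FALSE)
  expect_equal(rs$A, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rs$B, c(0, d, d), tolerance = 1e-12)
})

test_that("isotropic jitter of sigma per coordinate gives RMSD near sigma*sqrt(3)", {
  set.seed(9)
  n <- 10000L
  sigma <- 0.7
  base <- matrix(rnorm(3 * n, sd = 20), n, 3)
  sys <- toy_system(seq_len(n), base, atom_name = "CA")
  frames <- c(list(base),
              lapply(1:3, function(i) base + matrix(rnorm(3 * n, sd = sigma), n, 3)))
  traj <- toy_trajectory(sys, frames)
  rs <- rmsd_series(traj, list(all = domain_definition("all", list(c(1, n)))),
                    atom_filter = "all", fit = FALSE)
  expect_equal(mean(rs$all[-1]), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsd_series equals a naive per-frame double-loop recomputation", {
  spec <- synthetic_spec(domain_sizes = c(5, 5), seed = 10, n_frames = 6)
  sys <- build_synthetic_system(spec)
  traj <- simulate_trajectory(sys, spec)
  doms <- synthetic_domains(spec)
  rs <- rmsd_series(traj, doms, fit = FALSE)
  ref <- frame_coords(traj, 1)
  for (k in names(doms)) {
    sel <- resolve_selection(sys, doms[[k]], "backbone")
    for (i in seq_len(n_frames(traj))) {
      s <- 0
      for (a in as.integer(sel))
        s <- s + sum((frame_coords(traj, i)[a, ] - ref[a, ])^2)
      expect_equal(rs[[k]][i], sqrt(s / length(sel)), tolerance = 1e-12)
    }
  }
})

test_that("net displacement is 0 for static input and d*(n-1) under pure drift", {
  sys <- toy_system(1:3, matrix(rnorm(9), 3, 3))
  static <- toy_trajectory(sys, rep(list(coords(sys)), 5))
  sel <- resolve_selection(sys, NULL, "all")
  expect_equal(net_displacement(static, sel), 0)

  spec <- synthetic_spec(domain_sizes = c(5, 5), com_sigma = 0, jitter_sigma = 0,
                         ligand = list(drift = c(0, 0, 0.1), diffusion = 0),
                         seed = 11, n_frames = 100)
  s2 <- build_synthetic_system(spec)
  traj <- simulate_trajectory(s2, spec)
  lig <- atom_selection(which(s2$atoms$residue_name == "LIG"), "LIG")
  expect_equal(net_displacement(traj, lig), 9.9, tolerance = 1e-12)
})

test_that("net displacement under drift+diffusion matches direct centroid recomputation", {
  spec <- synthetic_spec(domain_sizes = c(5, 5), seed = 12, n_frames = 40,
                         ligand = list(drift = c(0.05, 0, 0.1), diffusion = 0.3))
  sys <- build_synthetic_system(spec)
  traj <- simulate_trajectory(sys, spec)
  lig <- atom_selection(which(sys$atoms$residue_name == "LIG"), "LIG")
  c1 <- colMeans(frame_coords(traj, 1)[lig, , drop = FALSE])
  cn <- colMeans(frame_coords(traj, 40)[lig, , drop = FALSE])
  expect_equal(net_displacement(traj, lig), sqrt(sum((cn - c1)^2)),
               tolerance = 1e-12)
  expect_error(net_displacement(traj, integer()), "empty")
})
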