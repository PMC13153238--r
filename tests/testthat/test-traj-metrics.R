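# Trajectory metrics: superposition, RMSD/RMSF/Rg/SASA, hydrogen bonds,
# PCA and free energy landscapes.

random_rotation <- function() {
  qr_r <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_r)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

test_that("Kabsch superposition handles identity, translation and the grid oracle", {
  set.seed(1)
  x <- matrix(stats::rnorm(30), 10, 3)
  fit <- kabschSuperpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  fit_t <- kabschSuperpose(sweep(x, 2, c(1, -2, 3), "+"), x)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)
  # reflections are excluded: proper rotation only
  expect_equal(det(fit_t$rotation), 1, tolerance = 1e-9)
  y <- matrix(stats::rnorm(30), 10, 3)
  fit_xy <- kabschSuperpose(x, y)
  expect_equal(fit_xy$rmsd, gridMinRmsd(x, y), tolerance = 1e-3)
  # symmetry of the minimized RMSD
  expect_equal(fit_xy$rmsd, kabschSuperpose(y, x)$rmsd, tolerance = 1e-9)
  collinear <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(kabschSuperpose(collinear, collinear + 1), "collinear")
})

test_that("RMSD series is zero for static trajectories and at the reference frame", {
  traj <- simulateTrajectory(n_atoms = 8, n_frames = 6)
  s <- rmsdSeries(traj)
  expect_equal(s$value, rep(0, 6), tolerance = 1e-10)
  traj2 <- simulateTrajectory(n_atoms = 8, n_frames = 12, noise_sd = 0.05, seed = 4)
  s2 <- rmsdSeries(traj2, reference_frame = 3)
  expect_equal(s2$value[3], 0, tolerance = 1e-10)
  expect_true(all(s2$value[-3] > 0))
})

test_that("RMSF matches the closed-form sinusoid amplitude a/sqrt(2)", {
  a <- 0.4
  traj <- simulateTrajectory(n_atoms = 6, n_frames = 64,
    modes = list(list(atom = 3, direction = c(1, 0, 0), amplitude = a)))
  vals <- rmsf(traj, selection = "all", fit = FALSE)
  expect_equal(vals[3], a / sqrt(2), tolerance = 1e-9)
  expect_equal(vals[-3], rep(0, 5), tolerance = 1e-10)
  # static trajectory: all zeros
  expect_equal(rmsf(simulateTrajectory(n_atoms = 5, n_frames = 4),
    selection = "all", fit = FALSE), rep(0, 5), tolerance = 1e-12)
  expect_warning(one <- rmsf(Trajectory(array(0, c(1, 5, 3))), selection = "all"),
    "single")
  expect_equal(one, rep(0, 5))
})

test_that("radius of gyration matches closed forms", {
  # two unit-mass points 2 nm apart
  coords <- array(0, c(1, 2, 3)); coords[1, 2, 1] <- 2
  expect_equal(radiusOfGyration(Trajectory(coords))$value, 1)
  # coincident atoms
  expect_equal(radiusOfGyration(Trajectory(array(1, c(2, 4, 3))))$value, c(0, 0))
  # uniform ring of radius R
  R <- 1.7; k <- 100
  ring <- array(0, c(1, k, 3))
  ring[1, , 1] <- R * cos(2 * pi * seq_len(k) / k)
  ring[1, , 2] <- R * sin(2 * pi * seq_len(k) / k)
  expect_equal(radiusOfGyration(Trajectory(ring))$value, R, tolerance = 1e-9)
})

test_that("SASA matches sphere closed forms", {
  lone <- array(0, c(1, 1, 3))
  atoms1 <- data.frame(name = "P", mass = 1, radius = 0.2)
  area <- sasa(Trajectory(lone, atoms1))$value
  expect_equal(area, 4 * pi * 0.34^2, tolerance = 0.01 * 4 * pi * 0.34^2)
  # two (essentially) coincident atoms jointly expose the area of one sphere
  two <- array(0, c(1, 2, 3)); two[1, 2, 1] <- 1e-6
  atoms2 <- data.frame(name = c("P", "P"), mass = 1, radius = 0.2)
  area2 <- sasa(Trajectory(two, atoms2))$value
  expect_equal(area2, 4 * pi * 0.34^2, tolerance = 0.02 * 4 * pi * 0.34^2)
  # far apart: sum of both spheres
  apart <- array(0, c(1, 2, 3)); apart[1, 2, 1] <- 5
  area3 <- sasa(Trajectory(apart, atoms2))$value
  expect_equal(area3, 2 * 4 * pi * 0.34^2, tolerance = 1e-6)
  # convergence in point count on a random cluster
  set.seed(9)
  cl <- array(stats::rnorm(15, sd = 0.2), c(1, 5, 3))
  atoms5 <- data.frame(name = rep("P", 5), mass = 1, radius = 0.15)
  a240 <- sasa(Trajectory(cl, atoms5), n_points = 240)$value
  a960 <- sasa(Trajectory(cl, atoms5), n_points = 960)$value
  a3840 <- sasa(Trajectory(cl, atoms5), n_points = 3840)$value
  # refinement shrinks the error in expectation; allow sampling slack
  expect_lt(abs(a960 - a3840), abs(a240 - a3840) + 0.005 * a3840)
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
})

test_that("hydrogen bonds follow the distance and angle criteria", {
  mk <- function(hpos, apos) {
    coords <- array(0, c(1, 3, 3))
    coords[1, 2, ] <- hpos
    coords[1, 3, ] <- apos
    atoms <- data.frame(name = c("D", "H", "A"), mass = 1, radius = 0.12,
      donor = c(TRUE, FALSE, FALSE), hydrogen = c(FALSE, TRUE, FALSE),
      acceptor = c(FALSE, FALSE, TRUE), base_pairing = c(TRUE, TRUE, TRUE),
      bonded_to = c(NA, 1L, NA))
    Trajectory(coords, atoms)
  }
  expect_equal(hbondCount(mk(c(0.1, 0, 0), c(0.30, 0, 0)))$value, 1)
  expect_equal(hbondCount(mk(c(0.1, 0, 0), c(0.40, 0, 0)))$value, 0)
  # 45 degree H-D-A angle at 0.30 nm
  h45 <- c(cos(pi / 4), sin(pi / 4), 0) * 0.1
  expect_equal(hbondCount(mk(h45, c(0.30, 0, 0)))$value, 0)
  # just inside both cutoffs still counts
  h29 <- c(cos(29 * pi / 180), sin(29 * pi / 180), 0) * 0.1
  expect_equal(hbondCount(mk(h29, c(0.349, 0, 0)))$value, 1)
  # base-pairing filter excludes unflagged acceptors
  traj <- mk(c(0.1, 0, 0), c(0.30, 0, 0))
  traj@atoms$base_pairing[3] <- FALSE
  expect_equal(suppressWarnings(
    hbondCount(traj, pair_filter = "base_pairing"))$value, 0)
  expect_warning(hbondCount(Trajectory(array(0, c(1, 2, 3)))), "no donor")
})

test_that("PCA concentrates variance on a single driven mode and conserves trace", {
  traj <- simulateTrajectory(n_atoms = 6, n_frames = 40,
    modes = list(list(atom = 2, direction = c(0, 1, 0), amplitude = 0.5)))
  pca <- pcaTrajectory(traj, selection = "all", fit = FALSE)
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_equal(colMeans(pca$projections), rep(0, ncol(pca$projections)),
    tolerance = 1e-10, ignore_attr = TRUE)
  # trace identity on a noisy trajectory
  traj2 <- simulateTrajectory(n_atoms = 5, n_frames = 30, noise_sd = 0.1, seed = 5)
  pca2 <- pcaTrajectory(traj2, selection = "all", fit = FALSE)
  flat <- matrix(aperm(traj2@coords, c(1, 3, 2)), nrow = 30)
  expect_equal(sum(pca2$eigenvalues), sum(diag(stats::cov(flat))),
    tolerance = 1e-9)
  expect_error(pcaTrajectory(Trajectory(array(0, c(1, 5, 3)))), "2 frames")
})

test_that("free energy landscapes have a zero modal bin and closed-form gaps", {
  # all frames in one bin
  proj <- matrix(0, 10, 2)
  fel1 <- felGrid(list(projections = proj), bins = 4)
  expect_equal(min(fel1$G, na.rm = TRUE), 0)
  expect_identical(sum(!is.na(fel1$G)), 1L)
  # two bins with counts (N, N/e): free energy gap of exactly 1 kT
  n1 <- 54; n2 <- round(54 / exp(1))
  proj2 <- rbind(matrix(c(-1, -1), n1, 2, byrow = TRUE),
    matrix(c(1, 1), n2, 2, byrow = TRUE))
  fel2 <- felGrid(list(projections = proj2), bins = 2)
  gvals <- sort(fel2$G[!is.na(fel2$G)])
  expect_equal(gvals[1], 0)
  expect_equal(gvals[2], -log(n2 / n1), tolerance = 1e-12)
  # uniform occupancy: all sampled bins at zero
  proj3 <- as.matrix(expand.grid(seq(0, 1, length.out = 4),
    seq(0, 1, length.out = 4)))
  fel3 <- felGrid(list(projections = proj3), bins = 4)
  expect_true(all(fel3$G[!is.na(fel3$G)] == 0))
})

test_that("metrics are invariant under global rigid motions", {
  set.seed(17)
  traj <- simulateTrajectory(n_atoms = 7, n_frames = 10, noise_sd = 0.08, seed = 7)
  traj@atoms$donor[1] <- TRUE
  traj@atoms$hydrogen[2] <- TRUE
  traj@atoms$acceptor[5] <- TRUE
  traj@atoms$bonded_to[2] <- 1L
  r <- random_rotation(); tr <- c(0.5, -1, 2)
  moved <- traj
  for (f in seq_len(nFrames(traj))) {
    moved@coords[f, , ] <- sweep(traj@coords[f, , ] %*% t(r), 2, tr, "+")
  }
  expect_equal(rmsdSeries(moved, selection = "all")$value,
    rmsdSeries(traj, selection = "all")$value, tolerance = 1e-9)
  expect_equal(rmsf(moved, selection = "all"), rmsf(traj, selection = "all"),
    tolerance = 1e-8)
  expect_equal(radiusOfGyration(moved)$value, radiusOfGyration(traj)$value,
    tolerance = 1e-9)
  # SASA uses a space-fixed sphere point set, so rotation invariance is
  # only approximate at finite n_points
  expect_equal(sasa(moved)$value, sasa(traj)$value, tolerance = 5e-3)
  expect_equal(hbondCount(moved)$value, hbondCount(traj)$value)
  expect_equal(pcaTrajectory(moved, selection = "all")$eigenvalues,
    pcaTrajectory(traj, selection = "all")$eigenvalues, tolerance = 1e-8)
})

test_that("concatenation fits frames to a shared reference and keeps provenance", {
  traj <- simulateTrajectory(n_atoms = 6, n_frames = 5, noise_sd = 0.02, seed = 3)
  both <- concatFitted(list(a = traj, b = traj))
  expect_identical(nFrames(both), 10L)
  expect_identical(both@provenance, rep(c("a", "b"), each = 5))
  # a pre-rotated copy aligns back onto the reference
  r <- random_rotation()
  rot <- traj
  for (f in 1:5) rot@coords[f, , ] <- traj@coords[f, , ] %*% t(r)
  cc <- concatFitted(list(orig = traj, rot = rot), selection = "all")
  expect_equal(cc@coords[6, , ], cc@coords[1, , ], tolerance = 1e-8)
  small <- simulateTrajectory(n_atoms = 4, n_frames = 5)
  expect_error(concatFitted(list(traj, small)), "mismatch")
})

test_that("trajectory tables round-trip through CSV", {
  traj <- simulateTrajectory(n_atoms = 4, n_frames = 3, noise_sd = 0.05, seed = 6)
  cp <- withr::local_tempfile(fileext = ".csv")
  ap <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(traj, cp, ap)
  back <- readTrajectory(cp, ap)
  expect_equal(back@coords, traj@coords, tolerance = 1e-6)
  expect_identical(nrow(atomInfo(back)), 4L)
})
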