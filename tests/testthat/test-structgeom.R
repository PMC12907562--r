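test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(101)
  x <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)

  rot <- rotation_about_z(0.8) %*%
    matrix(c(1, 0, 0, 0, cos(0.3), -sin(0.3), 0, sin(0.3), cos(0.3)),
           3, 3, byrow = TRUE)
  y <- x %*% t(rot) + matrix(c(5, -2, 11), nrow(x), 3, byrow = TRUE)
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("Kabsch rmsd on noisy planar pairs matches a rotation-grid oracle", {
  set.seed(202)
  x <- cbind(matrix(rnorm(20), ncol = 2), 0)     # planar points
  y <- x %*% t(rotation_about_z(0.6)) + 0.1 * cbind(matrix(rnorm(20), ncol = 2), 0)
  fit <- kabsch_superpose(x, y)

  # brute force over in-plane rotations after centering (the optimum is
  # planar because both sets are)
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  grid <- seq(0, 2 * pi, length.out = 20001)
  best <- min(vapply(grid, function(th) {
    sqrt(mean(rowSums((xc %*% t(rotation_about_z(th)) - yc)^2)))
  }, numeric(1)))
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
})

test_that("window-averaged structures equal the frame mean after fitting", {
  tr <- generate_trajectory(trajectory_spec(6L, 3L, per_residue_sd = 0,
                                            seed = 4L))
  avg <- average_structure(tr)
  expect_equal(as.matrix(avg$atoms[, c("x", "y", "z")]),
               tr$coords[1L, , ], ignore_attr = TRUE, tolerance = 1e-10)

  # two frames at +d and -d about a mean: the average recovers the mean
  base <- helical_trace(5L)
  set.seed(77)
  d <- matrix(rnorm(15, sd = 0.05), 5L, 3L)
  arr <- array(NA_real_, c(2L, 5L, 3L))
  arr[1L, , ] <- base + d
  arr[2L, , ] <- base - d
  atoms <- data.frame(chain = "L", resno = 1:5, resname = "ALA",
                      atom_name = "CA", element = "C",
                      x = base[, 1], y = base[, 2], z = base[, 3])
  tr2 <- clamp_trajectory(arr, atoms)
  avg2 <- average_structure(tr2)
  fit <- kabsch_superpose(as.matrix(avg2$atoms[, c("x", "y", "z")]), base)
  expect_lt(fit$rmsd, 0.01)  # residual is O(|d|^2)

  expect_error(average_structure(tr, window = c(100, 200)), "no frames")
})

test_that("averaged structures recover a planted mean within the sampling bound", {
  n <- 400L
  spec <- trajectory_spec(5L, n, per_residue_sd = 0.6, seed = 12L)
  tr <- generate_trajectory(spec)
  avg <- average_structure(tr)
  planted <- attr(tr, "mean_coords")
  fit <- kabsch_superpose(as.matrix(avg$atoms[, c("x", "y", "z")]), planted)
  # per-axis sd is 0.6/sqrt(3); mean-of-n error bound 3*sd/sqrt(n)
  expect_lt(fit$rmsd, 3 * 0.6 / sqrt(n))
})

test_that("RMSF is zero for static frames and matches the alternating closed form", {
  tr <- generate_trajectory(trajectory_spec(4L, 5L, per_residue_sd = 0,
                                            seed = 6L))
  expect_true(all(rmsf(tr) < 1e-12))

  # one residue of many alternating +/- a along z, the rest static; without
  # global motion the closed-form RMSF of the mover is exactly a
  n_res <- 60L; a <- 0.8; mover <- 30L
  base <- helical_trace(n_res)
  arr <- array(rep(base, each = 4L), c(4L, n_res, 3L))
  arr[c(1L, 3L), mover, 3L] <- base[mover, 3L] + a
  arr[c(2L, 4L), mover, 3L] <- base[mover, 3L] - a
  atoms <- data.frame(chain = "L", resno = seq_len(n_res), resname = "ALA",
                      atom_name = "CA", element = "C",
                      x = base[, 1], y = base[, 2], z = base[, 3])
  traj <- clamp_trajectory(arr, atoms)
  r0 <- rmsf(traj, superpose = FALSE)
  expect_equal(unname(r0[mover]), a, tolerance = 1e-12)
  expect_true(all(r0[-mover] == 0))
  # with superposition the fit is diluted only O(1/n_res)
  r <- rmsf(traj)
  expect_equal(unname(r[mover]), a, tolerance = 0.05)
  expect_lt(max(r[-mover]), 0.05)

  expect_error(rmsf(tr, selection = "Z"), "chain|no atoms|matches")
})

test_that("RMSF pools fluctuations over multiple windows and respects selections", {
  spec <- trajectory_spec(3L, 200L, per_residue_sd = c(0.5, 1, 2), seed = 9L)
  tr <- generate_trajectory(spec)
  both <- rmsf(tr, windows = list(c(0, 100), c(100, 200)))
  whole <- rmsf(tr)
  expect_equal(unname(both), unname(whole), tolerance = 0.15)
  sel <- rmsf(tr, selection = "L:2-3")
  expect_equal(names(sel), c("L:2", "L:3"))
})

test_that("cluster-wise RMSF statistics match hand arithmetic and a two-pass oracle", {
  m <- rbind(c(1, 1), c(3, 3))
  st <- rmsf_cluster_stats(m, labels = c(1, 1))
  expect_equal(st[["1"]]$mean, c(2, 2))
  expect_equal(st[["1"]]$sd, c(sqrt(2), sqrt(2)))

  same <- rmsf_cluster_stats(rbind(c(2, 5), c(2, 5)), labels = c(1, 1))
  expect_equal(same[["1"]]$sd, c(0, 0))

  single <- rmsf_cluster_stats(rbind(c(1, 2), c(5, 6)), labels = c(1, 2))
  expect_true(attr(single[["2"]], "singleton"))
  expect_equal(single[["2"]]$sd, c(0, 0))

  set.seed(33)
  big <- matrix(runif(50), 10, 5)
  lab <- rep(1:2, each = 5)
  st2 <- rmsf_cluster_stats(big, lab)
  for (cl in 1:2) {
    rows <- big[lab == cl, ]
    # streaming (one-pass) mean/variance oracle
    for (j in 1:5) {
      mu <- 0; m2 <- 0
      for (i in seq_len(nrow(rows))) {
        delta <- rows[i, j] - mu
        mu <- mu + delta / i
        m2 <- m2 + delta * (rows[i, j] - mu)
      }
      expect_equal(st2[[as.character(cl)]]$mean[j], mu, tolerance = 1e-12)
      expect_equal(st2[[as.character(cl)]]$sd[j],
                   sqrt(m2 / (nrow(rows) - 1)), tolerance = 1e-12)
    }
  }
})

test_that("SASA matches analytic sphere values", {
  lone <- clamp_structure(data.frame(
    chain = "A", resno = 1L, resname = "ALA", atom_name = "CA",
    element = "C", x = 0, y = 0, z = 0))
  a <- sasa(lone)
  expect_equal(attr(a, "total"), 4 * pi * 3.1^2, tolerance = 1e-6)

  far <- two_atom_structure(50)
  expect_equal(attr(sasa(far), "total"), 2 * 4 * pi * 3.1^2,
               tolerance = 1e-6)

  # two overlapping equal spheres vs the spherical-cap closed form
  d <- 3.5
  near <- two_atom_structure(d)
  expect_equal(attr(sasa(near), "total"), two_sphere_sasa(3.1, 3.1, d),
               tolerance = 0.01)

  expect_warning(z <- sasa(clamp_structure(
    data.frame(chain = character(0), resno = integer(0),
               resname = character(0), atom_name = character(0),
               element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0)))), "zero atoms")
  expect_equal(attr(z, "total"), 0)
})

test_that("SASA is invariant under global rotation and translation", {
  set.seed(55)
  atoms <- data.frame(chain = "A", resno = 1:8, resname = "ALA",
                      atom_name = "CA", element = sample(c("C", "N", "O"), 8,
                                                         replace = TRUE),
                      x = rnorm(8, sd = 3), y = rnorm(8, sd = 3),
                      z = rnorm(8, sd = 3))
  s1 <- attr(sasa(clamp_structure(atoms)), "total")
  rot <- rotation_about_z(1.1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot) + 7
  atoms2 <- atoms; atoms2$x <- xyz[, 1]; atoms2$y <- xyz[, 2]
  atoms2$z <- xyz[, 3]
  s2 <- attr(sasa(clamp_structure(atoms2)), "total")
  expect_lt(abs(s1 - s2) / s1, 0.005)
})

test_that("buried interface area matches the two-sphere cap formula and is monotone", {
  iso <- 4 * pi * 3.1^2
  # far apart: no burial
  expect_lt(abs(buried_interface_area(two_atom_structure(100), "A", "B")),
            1e-6)
  ds <- c(2.0, 3.0, 4.5, 6.0, 6.3)
  buried <- vapply(ds, function(d)
    buried_interface_area(two_atom_structure(d), "A", "B"), numeric(1))
  expect_true(all(diff(buried) <= 1e-9))   # non-increasing with separation
  analytic <- vapply(ds, function(d) 2 * iso - two_sphere_sasa(3.1, 3.1, d),
                     numeric(1))
  expect_equal(buried, analytic, tolerance = 0.01)

  expect_error(buried_interface_area(two_atom_structure(5), "A", "A"),
               "disjoint")
  expect_error(buried_interface_area(two_atom_structure(5), "A", "C"),
               "cover")
})
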