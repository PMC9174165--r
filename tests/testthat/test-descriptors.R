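test_that("Kabsch superposition removes rigid motions exactly", {
  ref <- rand_ref(8)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd_min, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation(3)
  mob <- sweep(ref %*% t(R), 2, c(5, -3, 2), `+`)
  fit <- kabsch_superpose(mob, ref)
  expect_equal(fit$rmsd_min, 0, tolerance = 1e-9)
  expect_equal(abs(det(fit$rotation)), 1, tolerance = 1e-9)
})

test_that("Kabsch result lower-bounds a random rigid-motion search", {
  set.seed(10)
  ref <- matrix(rnorm(12), 4, 3)
  mob <- matrix(rnorm(12), 4, 3)
  best <- kabsch_superpose(mob, ref)$rmsd_min
  cm_m <- colMeans(mob); cm_r <- colMeans(ref)
  P <- sweep(mob, 2, cm_m)
  worst <- min(vapply(1:5000, function(i) {
    R <- random_rotation(i)
    sqrt(mean(rowSums((sweep(P %*% t(R), 2, cm_r, `+`) - ref)^2)))
  }, numeric(1)))
  expect_lte(best, worst + 1e-12)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)),
               class = "vardyn_value_error")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(matrix(rnorm(15), 5, 3), line),
               class = "vardyn_value_error")
})

test_that("RMSD is zero on rigid motions and matches the direct formula", {
  ref <- rand_ref(6)
  const <- trajectory(ca_topology(6),
                      array(rep(ref, each = 5), dim = c(5, 6, 3)))
  expect_equal(rmsd_series(const, sel = 1:6)$values, rep(0, 5),
               tolerance = 1e-9)
  rigid <- apply_rigid(const, random_rotation(4), c(1, 2, 3))
  expect_equal(rmsd_series(rigid, sel = 1:6, ref = ref)$values, rep(0, 5),
               tolerance = 1e-9)
  # one atom displaced 1 A, fit disabled: RMSD = 1/sqrt(N)
  coords <- array(rep(ref, each = 2), dim = c(2, 6, 3))
  coords[2, 1, 1] <- coords[2, 1, 1] + 1
  tr <- trajectory(ca_topology(6), coords)
  r <- rmsd_series(tr, sel = 1:6, superpose = FALSE)
  expect_equal(r$values[2], 1 / sqrt(6), tolerance = 1e-12)
})

test_that("radius of gyration matches closed forms and the direct sum", {
  two <- trajectory(ca_topology(2),
                    matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(radius_of_gyration(two)$values, 1.0)
  one <- trajectory(ca_topology(1), matrix(c(3, 1, 4), 1, 3))
  expect_equal(radius_of_gyration(one)$values, 0)
  set.seed(20)
  pts <- matrix(rnorm(300), 100, 3)
  tr <- trajectory(ca_topology(100), array(pts, dim = c(1, 100, 3)))
  rg <- radius_of_gyration(tr)$values
  cm <- colMeans(pts)
  direct <- sqrt(sum(sweep(pts, 2, cm)^2) / 100)
  expect_equal(rg, direct, tolerance = 1e-10)
  # invariance under rigid motion
  rt <- apply_rigid(tr, random_rotation(6), c(-4, 2, 9))
  expect_equal(radius_of_gyration(rt)$values, rg, tolerance = 1e-9)
})

test_that("SASA matches the analytic sphere and splits overlaps evenly", {
  s <- sasa_frame(matrix(0, 1, 3), radii = 1.9)
  expect_equal(s$total, 4 * pi * (1.9 + 1.4)^2, tolerance = 1e-6)
  s2 <- sasa_frame(matrix(0, 2, 3), radii = c(1.9, 1.9))
  expect_equal(s2$per_atom[1], s2$per_atom[2])
  expect_equal(s2$total, 4 * pi * 3.3^2, tolerance = 0.01)
  expect_error(sasa_frame(matrix(0, 1, 3), radii = 1.9, n_points = 16),
               class = "vardyn_value_error")
  expect_error(sasa_frame(matrix(0, 1, 3), radii = -1),
               class = "vardyn_value_error")
})

test_that("SASA of a small cluster agrees with a dense-lattice evaluation", {
  fr <- matrix(c(0, 0, 0, 2.2, 0, 0, 1.1, 1.8, 0), 3, 3, byrow = TRUE)
  radii <- c(1.7, 1.55, 1.52)
  coarse <- sasa_frame(fr, radii)$total
  dense <- sasa_frame(fr, radii, n_points = 50000L)$total
  expect_equal(coarse, dense, tolerance = 0.01)
  # rotation/translation invariance at sampling tolerance
  R <- random_rotation(9)
  fr2 <- sweep(fr %*% t(R), 2, c(10, -5, 3), `+`)
  expect_equal(sasa_frame(fr2, radii)$total, coarse, tolerance = 0.01)
})

test_that("RMSF closed forms and frame-order invariance hold", {
  ref <- rand_ref(5)
  const <- trajectory(ca_topology(5),
                      array(rep(ref, each = 4), dim = c(4, 5, 3)))
  expect_equal(unname(rmsf(const, sel = 1:5)), rep(0, 5), tolerance = 1e-9)
  # two frames mirrored about the mean: RMSF = half the displacement
  coords <- array(rep(ref, each = 2), dim = c(2, 5, 3))
  coords[1, 2, 1] <- ref[2, 1] - 0.6
  coords[2, 2, 1] <- ref[2, 1] + 0.6
  tr <- trajectory(ca_topology(5), coords)
  f <- rmsf(tr, sel = 1:5, superpose = FALSE)
  expect_equal(unname(f[2]), 0.6, tolerance = 1e-12)
  # permutation of frames leaves RMSF unchanged
  jit <- gen_gaussian_ensemble(ref, 0.2, 60, seed = 14)
  perm <- trajectory(jit$topology, jit$coords[sample(60), , ])
  expect_equal(rmsf(jit, sel = 1:5), rmsf(perm, sel = 1:5),
               tolerance = 1e-9)
  expect_error(rmsf(trajectory(ca_topology(5), ref), sel = 1:5),
               class = "vardyn_value_error")
})

test_that("B-factor conversion is the 8*pi^2/3 parabola", {
  expect_equal(rmsf_to_bfactor(0), 0)
  expect_equal(rmsf_to_bfactor(1), 8 * pi^2 / 3)
  x <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(rmsf_to_bfactor(x)) > 0))
  expect_error(rmsf_to_bfactor(-0.1), class = "vardyn_value_error")
})

test_that("series densities integrate to one over their support", {
  set.seed(30)
  s <- series_summary(rnorm(2000, mean = 3))
  grid <- s$density$grid
  area <- sum(diff(grid) * (head(s$density$density, -1) +
                              tail(s$density$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_lte(min(grid), min(s$values))
  expect_gte(max(grid), max(s$values))
})
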