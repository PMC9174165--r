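test_that("DCCM recovers planted in-phase and anti-phase blocks", {
  ref <- rand_ref(10, sd = 6)
  tr <- gen_gaussian_ensemble(ref, planted_block_cov(), 3000, seed = 17)
  d <- dccm(tr, sel = 1:10, superpose = FALSE)
  expect_equal(d$c[1, 2], 1, tolerance = 0.02)
  expect_equal(d$c[3, 4], -1, tolerance = 0.02)
  off <- d$c[5:10, 5:10]; diag(off) <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 0.1)
})

test_that("DCCM equals a direct two-pass covariance oracle and bio3d", {
  ref <- rand_ref(8)
  tr <- gen_gaussian_ensemble(ref, 0.3, 400, seed = 23)
  d <- dccm(tr, sel = 1:8, superpose = FALSE)
  expect_equal(unname(d$c), dccm_oracle(tr$coords), tolerance = 1e-12)
  xyz <- t(apply(tr$coords, 1, function(m) as.vector(t(m))))
  expect_equal(unname(d$c), unname(bio3d::dccm.xyz(xyz)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("DCCM is bounded, symmetric and rigid-motion invariant", {
  ref <- rand_ref(6)
  tr <- gen_gaussian_ensemble(ref, 0.4, 300, seed = 29)
  d <- dccm(tr, sel = 1:6)
  expect_true(all(abs(d$c) <= 1 + 1e-9))
  expect_equal(d$c, t(d$c), tolerance = 1e-12)
  moved <- apply_rigid(tr, random_rotation(8), c(20, -7, 4))
  expect_equal(dccm(moved, sel = 1:6)$c, d$c, tolerance = 1e-6)
  # zero-variance atom flagged undefined, not zero
  coords <- tr$coords
  coords[, 1, ] <- rep(ref[1, ], each = 300)
  frozen <- trajectory(tr$topology, coords)
  dz <- dccm(frozen, sel = 1:6, superpose = FALSE)
  expect_true(all(is.na(dz$c[1, ])))
})

test_that("DCCM edge extraction filters and sorts by |c|", {
  cmat <- diag(3)
  cmat[1, 2] <- cmat[2, 1] <- 0.9
  cmat[1, 3] <- cmat[3, 1] <- -0.3
  cmat[2, 3] <- cmat[3, 2] <- 0.5
  d <- structure(list(residue_ids = c(11L, 12L, 13L), c = cmat),
                 class = "vd_dccm")
  expect_equal(nrow(dccm_edges(d, 1.01)), 0L)
  expect_equal(nrow(dccm_edges(d, 0)), 3L)
  e <- dccm_edges(d, 0.8)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$res_i, e$res_j), c(11L, 12L))
  expect_equal(dccm_edges(d, 0.2)$c, c(0.9, 0.5, -0.3))
})

test_that("PCA concentrates 1-D motion in the first mode", {
  ref <- rand_ref(5)
  Tn <- 200
  coords <- array(rep(ref, each = Tn), dim = c(Tn, 5, 3))
  coords[, 2, 1] <- coords[, 2, 1] + 2 * sin(2 * pi * (1:Tn) / 40)
  tr <- trajectory(ca_topology(5), coords)
  p <- suppressWarnings(pca_traj(tr, sel = 1:5, superpose = FALSE))
  expect_gte(p$eigenvalues[1] / p$trace, 0.99)
})

test_that("PCA satisfies its spectral identities", {
  ref <- rand_ref(6)
  tr <- gen_gaussian_ensemble(ref, 0.5, 600, seed = 37)
  p <- pca_traj(tr, sel = 1:6, superpose = FALSE)
  # trace = total per-coordinate variance computed independently
  X <- matrix(0, 600, 18)
  for (k in 1:3) X[, seq(k, 18, by = 3)] <- tr$coords[, , k]
  expect_equal(p$trace, sum(apply(X, 2, stats::var)), tolerance = 1e-10)
  # orthonormal eigenvectors
  G <- t(p$eigenvectors) %*% p$eigenvectors
  expect_equal(G, diag(18), tolerance = 1e-8)
  # projections: zero mean, diagonal covariance equal to eigenvalues
  expect_equal(colMeans(p$projections), rep(0, 18), tolerance = 1e-10)
  pc_cov <- stats::cov(p$projections)
  expect_equal(diag(pc_cov), p$eigenvalues, tolerance = 1e-8)
  pc_cov_off <- pc_cov; diag(pc_cov_off) <- 0
  expect_lt(max(abs(pc_cov_off)), 1e-8)
  # against the independent implementation
  xyz <- t(apply(tr$coords, 1, function(m) as.vector(t(m))))
  pb <- bio3d::pca.xyz(xyz)
  expect_equal(p$trace, sum(pb$L), tolerance = 1e-10)
  expect_equal(abs(sum(p$eigenvectors[, 1] * pb$U[, 1])), 1,
               tolerance = 1e-8)
})

test_that("planted low-rank covariance directions are recovered", {
  ref <- rand_ref(6)
  set.seed(41)
  v <- rnorm(18); v <- v / sqrt(sum(v^2))
  cov <- 4 * outer(v, v) + diag(0.01, 18)
  tr <- gen_gaussian_ensemble(ref, cov, 8000, seed = 43)
  p <- pca_traj(tr, sel = 1:6, superpose = FALSE)
  expect_gt(abs(sum(p$eigenvectors[, 1] * v)), 0.99)
})

test_that("RMSIP identities and the brute-force double sum agree", {
  ref <- rand_ref(7)
  a <- pca_traj(gen_gaussian_ensemble(ref, 0.3, 300, seed = 47),
                sel = 1:7, superpose = FALSE)
  b <- pca_traj(gen_gaussian_ensemble(ref, 0.6, 300, seed = 53),
                sel = 1:7, superpose = FALSE)
  expect_equal(rmsip(a, a), 1, tolerance = 1e-12)
  expect_equal(rmsip(a, b), rmsip(b, a), tolerance = 1e-12)
  brute <- sqrt(sum(outer(1:10, 1:10, Vectorize(function(i, j)
    sum(a$eigenvectors[, i] * b$eigenvectors[, j])^2))) / 10)
  expect_equal(rmsip(a, b, 10), brute, tolerance = 1e-12)
  # orthogonal subspaces
  o1 <- a; o1$eigenvectors <- diag(21)[, 1:10]
  o2 <- a; o2$eigenvectors <- diag(21)[, 11:20]
  expect_equal(rmsip(o1, o2, 10), 0, tolerance = 1e-12)
  expect_error(rmsip(a, b, n_modes = 50), class = "vardyn_value_error")
})

test_that("cosine content matches its analytic overlaps", {
  Tn <- 1000; t <- 0:(Tn - 1)
  expect_equal(cosine_content(cos(pi * t / Tn), 1), 1, tolerance = 1e-3)
  expect_lt(cosine_content(cos(2 * pi * t / Tn), 1), 1e-3)
  expect_equal(cosine_content(cos(2 * pi * t / Tn), 2), 1, tolerance = 1e-3)
  expect_error(cosine_content(c(1, 2, 3)), class = "vardyn_value_error")
  expect_true(is.na(cosine_content(rep(0, 100))))
  expect_true(is_convergent(0.05))
  expect_false(is_convergent(0.2))
})

test_that("porcupine and mode fluctuations respect normalisation", {
  ref <- rand_ref(5)
  tr <- gen_gaussian_ensemble(ref, 0.4, 400, seed = 59)
  p <- pca_traj(tr, sel = 1:5, superpose = FALSE)
  pq <- porcupine(p, mode = 1, scale = 0)
  expect_equal(pq$tip, pq$base)
  amp <- mode_fluctuation(p, 1)
  expect_equal(sum(amp^2), p$eigenvalues[1], tolerance = 1e-10)
  # single planted mode: amplitudes proportional to the construction
  v <- rep(0, 15); v[c(4, 7)] <- c(0.8, 0.6)
  cov <- 2 * outer(v, v)
  tr2 <- gen_gaussian_ensemble(ref, cov, 4000, seed = 61)
  p2 <- pca_traj(tr2, sel = 1:5, superpose = FALSE)
  amp2 <- mode_fluctuation(p2, 1)
  planted <- sqrt(rowSums(matrix(v, ncol = 3, byrow = TRUE)^2))
  cosim <- sum(amp2 * planted) / sqrt(sum(amp2^2) * sum(planted^2))
  expect_gt(cosim, 0.99)
})
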