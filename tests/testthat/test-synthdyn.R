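test_that("zero covariance reproduces the reference in every frame", {
  ref <- rand_ref(6)
  tr <- gen_gaussian_ensemble(ref, 0, 5, seed = 1)
  for (k in 1:5) expect_equal(frame_coords(tr, k), ref,
                              ignore_attr = TRUE)
})

test_that("generators are bit-reproducible for a fixed seed", {
  ref <- rand_ref(5)
  a <- gen_gaussian_ensemble(ref, 0.3, 50, seed = 99)
  b <- gen_gaussian_ensemble(ref, 0.3, 50, seed = 99)
  expect_identical(a$coords, b$coords)
  d1 <- gen_drift_ensemble(ref, ref * 0.001, 0.1, 30, seed = 5)
  d2 <- gen_drift_ensemble(ref, ref * 0.001, 0.1, 30, seed = 5)
  expect_identical(d1$coords, d2$coords)
  t1 <- gen_two_state_ensemble(ref, ref + 2, 0.5, 0.1, 40, seed = 7)
  t2 <- gen_two_state_ensemble(ref, ref + 2, 0.5, 0.1, 40, seed = 7)
  expect_identical(t1$coords, t2$coords)
  expect_identical(attr(t1, "state"), attr(t2, "state"))
})

test_that("isotropic Gaussian jitter has RMSF sqrt(3)*sigma", {
  ref <- rand_ref(10, sd = 8)
  tr <- gen_gaussian_ensemble(ref, 0.5^2, 6000, seed = 13)
  f <- rmsf(tr, sel = 1:10, superpose = FALSE)
  expect_equal(mean(f), sqrt(3) * 0.5, tolerance = 0.02)
})

test_that("sample covariance converges to the specified covariance", {
  ref <- rand_ref(4)
  cov <- planted_block_cov(0.25)[1:12, 1:12]
  tr <- gen_gaussian_ensemble(ref, cov, 30000, seed = 21)
  X <- matrix(0, 30000, 12)
  for (k in 1:3) X[, seq(k, 12, by = 3)] <- tr$coords[, , k]
  emp <- stats::cov(X)
  expect_lt(norm(emp - cov, "F") / norm(cov, "F"), 0.05)
})

test_that("non-PSD or asymmetric covariance is rejected", {
  ref <- rand_ref(2)
  bad <- diag(6); bad[1, 1] <- -1
  expect_error(gen_gaussian_ensemble(ref, bad, 5, seed = 1),
               class = "vardyn_value_error")
  asym <- diag(6); asym[1, 2] <- 0.5
  expect_error(gen_gaussian_ensemble(ref, asym, 5, seed = 1),
               class = "vardyn_value_error")
})

test_that("drift ensembles rise monotonically and look like diffusion", {
  ref <- rand_ref(8)
  flat <- gen_drift_ensemble(ref, ref * 0, 0, 10, seed = 2)
  expect_equal(max(abs(sweep(flat$coords, c(2, 3), ref))), 0)
  dr <- gen_drift_ensemble(ref, matrix(c(0.05, 0, 0), 8, 3, byrow = TRUE),
                           0, 50, seed = 3)
  r <- rmsd_series(dr, sel = 1:8, superpose = FALSE)
  expect_true(all(diff(r$values) > 0))
  # PC-1 of a drifting ensemble projects onto a half-period cosine
  noisy <- gen_drift_ensemble(ref, matrix(rnorm(24, sd = 0.02), 8, 3),
                              0.05, 400, seed = 4)
  p <- pca_traj(noisy)
  expect_gt(cosine_content(p$projections[, 1], 1), 0.9)
})

test_that("two-state ensembles respect occupancy and reject degenerate p", {
  ref <- rand_ref(5)
  expect_error(gen_two_state_ensemble(ref, ref + 1, 1, 0.1, 10, seed = 1),
               class = "vardyn_value_error")
  expect_error(gen_two_state_ensemble(ref, ref + 1, 0.5, -0.1, 10, seed = 1),
               class = "vardyn_value_error")
  tr <- gen_two_state_ensemble(ref, ref + 4, 0.7, 0.1, 10000, seed = 6)
  expect_equal(mean(attr(tr, "state") == "A"), 0.7, tolerance = 0.02)
})

test_that("ideal peptides are assigned their constructing pattern", {
  h <- build_ideal_peptide(12, "H")
  lab <- assign_ss(frame_coords(h), h$topology)
  expect_true(all(lab[3:10] == "H"))
  g <- build_ideal_peptide(8, "G")
  labg <- assign_ss(frame_coords(g), g$topology)
  expect_true(all(labg[3:6] == "G"))
  e <- build_ideal_peptide(8, "E", pair = "antiparallel")
  labe <- assign_ss(frame_coords(e), e$topology)
  expect_true(all(labe[c(4:6, 12:14)] == "E"))
  # a lone extended strand has no bridge partner, hence no E
  lone <- build_ideal_peptide(8, "E")
  expect_false(any(assign_ss(frame_coords(lone), lone$topology) == "E"))
  expect_error(build_ideal_peptide(3, "H"), class = "vardyn_value_error")
  expect_error(build_ideal_peptide(8, "HHXXHHHH"),
               class = "vardyn_value_error")
})

test_that("call-table generation matches its declared vote counts", {
  all_del <- gen_call_table(1, 17, 1, seed = 1)
  expect_equal(vote_counts(all_del$table)$votes, 17L)
  none <- gen_call_table(1, 17, 0, seed = 1)
  expect_equal(vote_counts(none$table)$votes, 0L)
  g <- gen_call_table(1000, 17, 0.5, seed = 31)
  expect_identical(vote_counts(g$table)$votes, as.integer(g$truth_counts))
  g2 <- gen_call_table(1000, 17, 0.5, seed = 31)
  expect_identical(g$table$calls, g2$table$calls)
})
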