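# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no stored binary data.

rand_ref <- function(n, sd = 5, seed = 42) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

# 3N x 3N covariance with planted residue blocks for 10 atoms:
# atoms 1-2 fully in phase, atoms 3-4 fully anti-phase, atoms 5-10
# independent isotropic. sigma2 is the per-axis variance.
planted_block_cov <- function(sigma2 = 0.25) {
  n <- 10L
  cov <- diag(sigma2, 3L * n)
  ax <- function(i) 3L * (i - 1L) + 1:3
  for (k in 1:3) {
    cov[ax(1)[k], ax(2)[k]] <- cov[ax(2)[k], ax(1)[k]] <- sigma2
    cov[ax(3)[k], ax(4)[k]] <- cov[ax(4)[k], ax(3)[k]] <- -sigma2
  }
  cov
}

# Independent two-pass DCCM oracle: explicit per-pair displacement
# covariance computed directly from the coordinate array.
dccm_oracle <- function(coords) {
  n <- dim(coords)[2]
  means <- apply(coords, c(2, 3), mean)
  num <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- sweep(coords[, i, ], 2, means[i, ])
    for (j in i:n) {
      dj <- sweep(coords[, j, ], 2, means[j, ])
      num[i, j] <- num[j, i] <- sum(di * dj) / (dim(coords)[1] - 1L)
    }
  }
  v <- diag(num)
  num / sqrt(outer(v, v))
}

# Trajectory whose frames alternate deterministically between a helical and a
# coil conformation of the same 12-residue peptide, with exactly
# round(frac * n_frames) helix frames, interleaved.
planted_helix_trajectory <- function(n_frames = 100L, frac = 0.4) {
  helix <- build_ideal_peptide(12, "H")
  coil <- build_ideal_peptide(12, "C")
  n_h <- round(frac * n_frames)
  is_helix <- rep(FALSE, n_frames)
  is_helix[seq_len(n_h) * floor(n_frames / n_h)] <- TRUE
  coords <- array(0, dim = c(n_frames, n_atoms(helix), 3L))
  for (k in seq_len(n_frames)) {
    coords[k, , ] <- frame_coords(if (is_helix[k]) helix else coil)
  }
  trajectory(helix$topology, coords)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(traj, R, shift) {
  coords <- traj$coords
  for (k in seq_len(n_frames(traj))) {
    coords[k, , ] <- sweep(frame_coords(traj, k) %*% t(R), 2, shift, `+`)
  }
  trajectory(traj$topology, coords, times = traj$times)
}
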