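# Synthetic ensembles with known ground truth.
#
# These generators emulate the statistical features of equilibrated MD
# ensembles that the analysis stages consume -- stationary Gaussian
# fluctuation about a reference, pre-equilibration drift, two-basin
# conformational switching, ideal secondary-structure geometry, persistent
# contacts, and predictor call tables -- without running any dynamics.
# Every generator takes an integer seed and is bit-reproducible; each call
# uses one fresh Mersenne-Twister stream.
#
# Coordinate vectors are atom-major: component 3*(i-1)+k is axis k of atom i.

#' Cα-only topology for synthetic ensembles
#'
#' Poly-alanine Cα topology with residues numbered from \code{first_resid}.
#'
#' @param n number of residues/atoms
#' @param first_resid residue number of the first residue (default 1)
#' @param chain chain identifier
#' @return topology data.frame usable with \code{\link{trajectory}}
#' @export
ca_topology <- function(n, first_resid = 1L, chain = "A") {
  data.frame(atom_name = rep("CA", n), element = rep("C", n),
             resid = first_resid + seq_len(n) - 1L,
             resname = rep("ALA", n), chain = rep(chain, n),
             stringsAsFactors = FALSE)
}

#' Evaluate an expression under a private RNG stream
#'
#' Seeds the generator, evaluates \code{expr}, and restores the caller's RNG
#' state, so seeded fixtures never perturb surrounding randomness.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of \code{expr}
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stationary Gaussian ensemble with a prescribed covariance
#'
#' Draws \code{n_frames} i.i.d. frames from a multivariate normal centred on
#' \code{reference} with the given \code{3N x 3N} positional covariance
#' (Angstrom^2, atom-major ordering). This is the stand-in for an equilibrated
#' ensemble with known correlation structure: a planted block covariance
#' produces known DCCM entries and PCA eigenvectors downstream.
#'
#' @param reference N x 3 matrix, Angstrom
#' @param covariance 3N x 3N symmetric positive semidefinite matrix
#'   (Angstrom^2), or a single number for isotropic \code{sigma^2 I}
#' @param n_frames number of frames (>= 2)
#' @param seed integer seed
#' @param topology optional topology; defaults to \code{ca_topology(N)}
#' @param dt frame spacing in ns
#' @return a \code{vd_trajectory}
#' @export
gen_gaussian_ensemble <- function(reference, covariance, n_frames, seed,
                                  topology = NULL, dt = 0.1) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  d <- 3L * n
  if (n_frames < 2L) vd_error("n_frames must be >= 2", "vardyn_value_error")
  if (length(covariance) == 1L) covariance <- diag(covariance, d)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8))) {
    vd_error("covariance must be symmetric", "vardyn_value_error")
  }
  es <- eigen(covariance, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values), 1)) {
    vd_error("covariance is not positive semidefinite", "vardyn_value_error")
  }
  lam <- pmax(es$values, 0)
  L <- es$vectors %*% diag(sqrt(lam), d)
  ref_vec <- as.vector(t(reference))  # atom-major
  X <- with_seed(seed, matrix(stats::rnorm(n_frames * d), n_frames, d))
  disp <- X %*% t(L)
  coords <- array(0, dim = c(n_frames, n, 3L))
  for (k in 1:3) coords[, , k] <- sweep(disp[, seq(k, d, by = 3L),
                                             drop = FALSE],
                                        2, ref_vec[seq(k, d, by = 3L)], `+`)
  if (is.null(topology)) topology <- ca_topology(n)
  trajectory(topology, coords, dt = dt)
}

#' Drifting ensemble emulating pre-equilibration relaxation
#'
#' Frame k (0-based) is \code{reference + k * drift_per_frame} plus isotropic
#' Gaussian noise, producing a monotone RMSD rise like the first ~100 ns of an
#' unequilibrated MD run; its dominant principal component projects onto a
#' half-period cosine (high cosine content).
#'
#' @param reference N x 3 matrix, Angstrom
#' @param drift_per_frame N x 3 matrix, Angstrom per frame
#' @param noise_sigma isotropic noise s.d. per coordinate, Angstrom
#' @param n_frames number of frames
#' @param seed integer seed
#' @param topology optional topology
#' @param dt frame spacing in ns
#' @return a \code{vd_trajectory}
#' @export
gen_drift_ensemble <- function(reference, drift_per_frame, noise_sigma,
                               n_frames, seed, topology = NULL, dt = 0.1) {
  reference <- as.matrix(reference)
  drift_per_frame <- as.matrix(drift_per_frame)
  stopifnot(all(dim(reference) == dim(drift_per_frame)))
  n <- nrow(reference)
  coords <- array(0, dim = c(n_frames, n, 3L))
  noise <- with_seed(seed, array(stats::rnorm(n_frames * n * 3L,
                                              sd = noise_sigma),
                                 dim = c(n_frames, n, 3L)))
  for (k in seq_len(n_frames)) {
    coords[k, , ] <- reference + (k - 1L) * drift_per_frame + noise[k, , ]
  }
  if (is.null(topology)) topology <- ca_topology(n)
  trajectory(topology, coords, dt = dt)
}

#' Two-basin ensemble for free-energy-landscape tests
#'
#' Each frame is assigned to state A with probability \code{p_a} (seeded
#' Bernoulli) and jittered with isotropic Gaussian noise about that state's
#' reference, emulating two conformational basins with a known occupancy
#' ratio; the Boltzmann-inverted free-energy gap between the basins is then
#' \code{kT * log(p_a / (1 - p_a))} in expectation.
#'
#' @param ref_a,ref_b N x 3 matrices, Angstrom
#' @param p_a probability of state A, strictly inside (0, 1)
#' @param noise_sigma isotropic jitter s.d., Angstrom (>= 0)
#' @param n_frames number of frames
#' @param seed integer seed
#' @param topology optional topology
#' @param dt frame spacing in ns
#' @return a \code{vd_trajectory} with attribute \code{state} ("A"/"B" per
#'   frame)
#' @export
gen_two_state_ensemble <- function(ref_a, ref_b, p_a, noise_sigma, n_frames,
                                   seed, topology = NULL, dt = 0.1) {
  if (!(p_a > 0 && p_a < 1)) vd_error("p_a must be strictly inside (0,1)",
                                      "vardyn_value_error")
  if (noise_sigma < 0) vd_error("noise_sigma must be >= 0",
                                "vardyn_value_error")
  ref_a <- as.matrix(ref_a); ref_b <- as.matrix(ref_b)
  stopifnot(all(dim(ref_a) == dim(ref_b)))
  n <- nrow(ref_a)
  out <- with_seed(seed, {
    st <- stats::rbinom(n_frames, 1L, p_a)
    noise <- array(stats::rnorm(n_frames * n * 3L, sd = noise_sigma),
                   dim = c(n_frames, n, 3L))
    list(st = st, noise = noise)
  })
  coords <- array(0, dim = c(n_frames, n, 3L))
  for (k in seq_len(n_frames)) {
    base <- if (out$st[k] == 1L) ref_a else ref_b
    coords[k, , ] <- base + out$noise[k, , ]
  }
  if (is.null(topology)) topology <- ca_topology(n)
  traj <- trajectory(topology, coords, dt = dt)
  attr(traj, "state") <- ifelse(out$st == 1L, "A", "B")
  traj
}

# ---- ideal peptide geometry ------------------------------------------------

# Standard backbone internal coordinates (Angstrom, degrees).
PEPTIDE_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8,
  omega = 180)

# Ideal (phi, psi) per secondary-structure code.
SS_TORSIONS <- list(H = c(-57, -47), G = c(-49, -26), E = c(-119, 113),
                    C = c(-75, 145))

deg2rad <- function(x) x * pi / 180

# Place atom D given positions A, B, C and internal coordinates
# |CD| = bond, angle(BCD) = ang (deg), torsion(ABCD) = tor (deg).
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang); tor <- deg2rad(tor)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- vd_cross(bc, n)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * (-n) + d2[3] * (-m)
}

vd_cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])

backbone_topology <- function(n_res, first_resid = 1L, chain = "A") {
  data.frame(
    atom_name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resid = rep(first_resid + seq_len(n_res) - 1L, each = 4L),
    resname = rep("ALA", 4L * n_res),
    chain = rep(chain, 4L * n_res),
    stringsAsFactors = FALSE)
}

build_backbone_coords <- function(phi, psi) {
  g <- PEPTIDE_GEOM
  n_res <- length(phi)
  pos <- matrix(0, nrow = 4L * n_res, ncol = 3L)  # N, CA, C, O per residue
  idx <- function(i, atom) (i - 1L) * 4L +
    match(atom, c("N", "CA", "C", "O"))
  # first residue in the xy-plane
  pos[idx(1, "N"), ] <- c(0, 0, 0)
  pos[idx(1, "CA"), ] <- c(g$b_N_CA, 0, 0)
  ang <- deg2rad(g$a_N_CA_C)
  pos[idx(1, "C"), ] <- pos[idx(1, "CA"), ] +
    g$b_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      pos[idx(i, "N"), ] <- place_atom(pos[idx(i - 1L, "N"), ],
                                       pos[idx(i - 1L, "CA"), ],
                                       pos[idx(i - 1L, "C"), ],
                                       g$b_C_N, g$a_CA_C_N, psi[i - 1L])
      pos[idx(i, "CA"), ] <- place_atom(pos[idx(i - 1L, "CA"), ],
                                        pos[idx(i - 1L, "C"), ],
                                        pos[idx(i, "N"), ],
                                        g$b_N_CA, g$a_C_N_CA, g$omega)
      pos[idx(i, "C"), ] <- place_atom(pos[idx(i - 1L, "C"), ],
                                       pos[idx(i, "N"), ],
                                       pos[idx(i, "CA"), ],
                                       g$b_CA_C, g$a_N_CA_C, phi[i])
    }
    # carbonyl O: torsion N-CA-C-O = psi + 180 (O anti to the next N)
    pos[idx(i, "O"), ] <- place_atom(pos[idx(i, "N"), ],
                                     pos[idx(i, "CA"), ],
                                     pos[idx(i, "C"), ],
                                     g$b_C_O, g$a_CA_C_O, psi[i] + 180)
  }
  pos
}

rotate_about_axis <- function(coords, center, axis, angle_deg) {
  th <- deg2rad(angle_deg)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(coords, 2, center) %*% t(R), 2, center, `+`)
}

# Amide hydrogen positions for a 4-atoms/residue backbone strand: 1.0 A from
# N opposite the C(i-1)-N-CA bisector; residue 1 has none (NA row).
strand_amide_H <- function(coords, n_res) {
  idx <- function(i, k) (i - 1L) * 4L + k  # k: 1=N 2=CA 3=C 4=O
  H <- matrix(NA_real_, n_res, 3L)
  for (i in 2:n_res) {
    n <- coords[idx(i, 1L), ]
    u1 <- coords[idx(i - 1L, 3L), ] - n; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- coords[idx(i, 2L), ] - n; u2 <- u2 / sqrt(sum(u2^2))
    dir <- -(u1 + u2); dir <- dir / sqrt(sum(dir^2))
    H[i, ] <- n + dir
  }
  H
}

# Place a duplicate strand next to `coords` (4 atoms/residue backbone) so the
# two strands pair as a beta-sheet. The partner is generated by the sheet's
# local two-fold symmetry (antiparallel) or pure translation (parallel) and
# positioned by a deterministic grid search over inter-strand separation and
# axial register that maximises the number of ideal inter-chain hydrogen
# bonds (amide H ... carbonyl O near 1.95 Angstrom) without steric clashes.
pair_strand <- function(coords, n_res, orientation = "antiparallel") {
  idx <- function(i, k) (i - 1L) * 4L + k  # k: 1=N 2=CA 3=C 4=O
  ca <- coords[idx(seq_len(n_res), 2L), , drop = FALSE]
  axis <- ca[n_res, ] - ca[1, ]
  axis <- axis / sqrt(sum(axis^2))
  center <- colMeans(ca)
  # sheet-plane direction: mean alternating carbonyl direction off the axis
  co <- coords[idx(seq_len(n_res), 4L), , drop = FALSE] -
    coords[idx(seq_len(n_res), 3L), , drop = FALSE]
  co_alt <- co * rep_len(c(1, -1), n_res)
  perp <- colMeans(co_alt)
  perp <- perp - sum(perp * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  Ha <- strand_amide_H(coords, n_res)
  Os <- coords[idx(seq_len(n_res), 4L), , drop = FALSE]
  okH <- !is.na(Ha[, 1])
  cross_d <- function(P, Q) {
    sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q), 0))
  }
  score_fn <- function(other, otherH) {
    oO <- other[idx(seq_len(n_res), 4L), , drop = FALSE]
    if (min(cross_d(coords, other)) < 2.4) return(NULL)  # steric clash
    d1 <- cross_d(Ha[okH, , drop = FALSE], oO)            # A donates to B
    d2 <- cross_d(otherH[okH, , drop = FALSE], Os)        # B donates to A
    dd <- abs(c(d1, d2) - 1.95)
    list(hits = sum(dd < 0.4), misfit = sum(pmin(dd, 1)))
  }
  best <- NULL
  for (rot_axis in if (orientation == "antiparallel")
    list(perp, vd_cross(axis, perp)) else list(NULL)) {
    base <- coords
    if (!is.null(rot_axis)) base <- rotate_about_axis(coords, center,
                                                      rot_axis, 180)
    baseH <- strand_amide_H(base, n_res)
    for (sep in c(seq(3.6, 6.2, by = 0.1), seq(-6.2, -3.6, by = 0.1))) {
      for (shift in seq(-4, 4, by = 0.1)) {
        off <- sep * perp + shift * axis
        cand <- sweep(base, 2, off, `+`)
        sc <- score_fn(cand, sweep(baseH, 2, off, `+`))
        if (!is.null(sc) && (is.null(best) || sc$hits > best$hits ||
            (sc$hits == best$hits && sc$misfit < best$misfit - 1e-9))) {
          best <- list(hits = sc$hits, misfit = sc$misfit, coords = cand)
        }
      }
    }
  }
  if (is.null(best)) vd_error("strand pairing failed", "vardyn_value_error")
  best$coords
}

#' Build an ideal-geometry peptide with a prescribed conformation
#'
#' Constructs a poly-alanine backbone (N, CA, C, O per residue) from ideal
#' bond lengths/angles and the canonical torsions for each secondary-structure
#' code: \code{H} alpha-helix (phi,psi) = (-57, -47); \code{G} 3-10 helix
#' (-49, -26); \code{E} beta-strand (-119, 113); \code{C} extended irregular
#' coil. With \code{pair = "antiparallel"} or \code{"parallel"} a duplicate
#' strand is positioned alongside (chain B) with ideal inter-chain
#' hydrogen-bond geometry, so that bridge-pattern assignment has a partner.
#'
#' @param n_res number of residues (>= 4)
#' @param ss_pattern string over \code{H, G, E, C}; a single character is
#'   recycled to \code{n_res}
#' @param pair one of \code{"none"}, \code{"antiparallel"}, \code{"parallel"}
#' @param first_resid residue number of the first residue
#' @return single-frame \code{vd_trajectory}
#' @export
build_ideal_peptide <- function(n_res, ss_pattern, pair = "none",
                                first_resid = 1L) {
  if (n_res < 4L) vd_error("n_res must be >= 4", "vardyn_value_error")
  codes <- strsplit(ss_pattern, "")[[1]]
  if (length(codes) == 1L) codes <- rep(codes, n_res)
  if (length(codes) != n_res) {
    vd_error("ss_pattern length must be 1 or n_res", "vardyn_value_error")
  }
  if (!all(codes %in% names(SS_TORSIONS))) {
    vd_error("ss_pattern codes must be in {H, G, E, C}", "vardyn_value_error")
  }
  tor <- vapply(codes, function(cc) SS_TORSIONS[[cc]], numeric(2))
  coords <- build_backbone_coords(phi = tor[1, ], psi = tor[2, ])
  topo <- backbone_topology(n_res, first_resid = first_resid)
  if (pair != "none") {
    if (!pair %in% c("antiparallel", "parallel")) {
      vd_error("pair must be none/antiparallel/parallel", "vardyn_value_error")
    }
    partner <- pair_strand(coords, n_res, orientation = pair)
    topo2 <- backbone_topology(n_res, first_resid = first_resid, chain = "B")
    coords <- rbind(coords, partner)
    topo <- rbind(topo, topo2)
  }
  trajectory(topo, coords)
}

# ---- predictor call tables -------------------------------------------------

#' Construct a call table
#'
#' @param snp_ids character vector of variant identifiers (unique)
#' @param tool_names character vector of predictor names (unique)
#' @param calls S x K matrix over \{0, 1, NA\} (1 = called deleterious)
#' @param scores optional S x K numeric matrix of raw tool scores
#' @return object of class \code{vd_call_table}
#' @export
call_table <- function(snp_ids, tool_names, calls, scores = NULL) {
  calls <- as.matrix(calls)
  if (anyDuplicated(snp_ids) || anyDuplicated(tool_names)) {
    vd_error("snp_ids and tool_names must be unique", "vardyn_value_error")
  }
  if (nrow(calls) != length(snp_ids) || ncol(calls) != length(tool_names)) {
    vd_error("calls matrix shape must be n_snps x n_tools",
             "vardyn_value_error")
  }
  if (!all(calls %in% c(0, 1) | is.na(calls))) {
    vd_error("calls must be 0, 1 or NA", "vardyn_value_error")
  }
  dimnames(calls) <- list(snp_ids, tool_names)
  structure(list(snp_ids = as.character(snp_ids),
                 tool_names = as.character(tool_names),
                 calls = calls, scores = scores),
            class = "vd_call_table")
}

#' Generate a random predictor call table with known vote counts
#'
#' Seeded Bernoulli calls: entry (s, k) is deleterious with probability
#' \code{p_deleterious[s, k]} (a vector is recycled across tools, a scalar
#' across everything). Ground-truth vote counts are returned alongside.
#'
#' @param n_snps,n_tools table dimensions
#' @param p_deleterious scalar, per-SNP vector, or S x K matrix of
#'   probabilities in [0, 1]
#' @param seed integer seed
#' @return list with elements \code{table} (a \code{vd_call_table}) and
#'   \code{truth_counts} (per-SNP integer vote counts)
#' @export
gen_call_table <- function(n_snps, n_tools, p_deleterious, seed) {
  p <- p_deleterious
  if (is.matrix(p)) {
    stopifnot(nrow(p) == n_snps, ncol(p) == n_tools)
  } else if (length(p) == 1L) {
    p <- matrix(p, n_snps, n_tools)
  } else {
    stopifnot(length(p) == n_snps)
    p <- matrix(rep(p, n_tools), n_snps, n_tools)
  }
  if (any(p < 0 | p > 1)) vd_error("probabilities must lie in [0,1]",
                                   "vardyn_value_error")
  calls <- with_seed(seed,
                     matrix(stats::rbinom(n_snps * n_tools, 1L, as.vector(p)),
                            n_snps, n_tools))
  tab <- call_table(sprintf("snp%04d", seq_len(n_snps)),
                    sprintf("tool%02d", seq_len(n_tools)), calls)
  list(table = tab, truth_counts = rowSums(calls))
}
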