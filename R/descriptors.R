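# Ensemble descriptors: least-squares superposition, RMSD, radius of
# gyration, Shrake-Rupley solvent-accessible surface area, RMSF and the
# crystallographic B-factor conversion, plus kernel-density summaries of
# per-frame series.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
ATOMIC_MASSES <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                   P = 30.974)

element_radii <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

element_masses <- function(elements) {
  m <- ATOMIC_MASSES[toupper(elements)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Summarise a per-frame descriptor series
#'
#' Computes the mean and a Gaussian-kernel density estimate (Silverman
#' bandwidth, 512-point grid) of a per-frame series, the numeric form of the
#' smoothed density plots used to compare variant and wild-type ensembles.
#'
#' @param values numeric per-frame vector
#' @param times optional per-frame times (ns)
#' @param unit unit label carried through for reporting
#' @return object of class \code{vd_series} with fields \code{values},
#'   \code{times}, \code{mean}, \code{density} (grid/density), \code{unit}
#' @export
series_summary <- function(values, times = NULL, unit = "") {
  values <- as.numeric(values)
  dens <- if (length(unique(values)) > 1L) {
    d <- stats::density(values, bw = "nrd0", n = 512)
    list(grid = d$x, density = d$y)
  } else {
    list(grid = values[1], density = Inf)
  }
  structure(list(values = values, times = times, mean = mean(values),
                 median = stats::median(values),
                 quartiles = stats::quantile(values, c(0.25, 0.75),
                                             names = FALSE),
                 density = dens, unit = unit),
            class = "vd_series")
}

#' @export
print.vd_series <- function(x, ...) {
  cat(sprintf("<vd_series> n=%d mean=%.4g %s\n", length(x$values), x$mean,
              x$unit))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between \code{mobile} and \code{ref}; reflections are
#' corrected so \code{det(rotation) = +1}.
#'
#' @param mobile,ref N x 3 coordinate matrices (Angstrom), N >= 3,
#'   non-degenerate reference
#' @param weights optional per-atom non-negative weights
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd_min} (Angstrom) and \code{transformed} (mobile mapped onto
#'   ref: \code{t(R \%*\% t(mobile - cm_mob)) + cm_ref})
#' @export
kabsch_superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n < 3L || nrow(ref) != n) vd_error("need >= 3 paired atoms",
                                         "vardyn_value_error")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) vd_error("invalid weights",
                                          "vardyn_value_error")
  wn <- w / sum(w)
  cm_m <- colSums(mobile * wn)
  cm_r <- colSums(ref * wn)
  P <- sweep(mobile, 2, cm_m)
  Q <- sweep(ref, 2, cm_r)
  sv_ref <- svd(Q * sqrt(wn))$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    vd_error("degenerate (collinear) reference geometry",
             "vardyn_value_error")
  }
  H <- t(P * wn) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(P %*% t(R), 2, cm_r, `+`)
  rmsd_min <- sqrt(sum(wn * rowSums((transformed - ref)^2)))
  list(rotation = R, translation = cm_r - as.vector(R %*% cm_m),
       rmsd_min = rmsd_min, transformed = transformed)
}

# Superpose every frame of a T x N x 3 array onto ref over the atoms in
# `fit_idx`, applying the fitted rigid motion to all atoms.
superpose_frames <- function(coords, ref, fit_idx = seq_len(dim(coords)[2])) {
  out <- coords
  for (k in seq_len(dim(coords)[1])) {
    fr <- matrix(coords[k, , ], ncol = 3L)
    fit <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
    out[k, , ] <- sweep(fr %*% t(fit$rotation), 2, fit$translation, `+`)
  }
  out
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is least-squares superposed onto the reference over the
#' selection, and the RMSD over that selection reported. The conventional
#' reference is the first frame of a replica, so the series tracks
#' equilibration drift and plateau.
#'
#' @param traj a \code{vd_trajectory}
#' @param sel atom index vector (default: backbone atoms)
#' @param ref N x 3 reference coordinates (default: first frame)
#' @param superpose logical; set \code{FALSE} to compute raw coordinate RMSD
#' @return a \code{vd_series} in Angstrom
#' @export
rmsd_series <- function(traj, sel = select_atoms(traj, "backbone"),
                        ref = frame_coords(traj, 1L), superpose = TRUE) {
  if (length(sel) == 0L) vd_error("empty selection", "vardyn_empty_selection")
  refs <- as.matrix(ref)[sel, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- matrix(traj$coords[k, sel, ], ncol = 3L)
    if (superpose) {
      kabsch_superpose(fr, refs)$rmsd_min
    } else {
      sqrt(mean(rowSums((fr - refs)^2)))
    }
  }, numeric(1))
  series_summary(vals, times = traj$times, unit = "A")
}

#' Radius of gyration
#'
#' \eqn{Rg = \sqrt{\sum_i w_i |r_i - r_{cm}|^2 / \sum_i w_i}} with unit
#' weights by default or atomic masses when \code{mass_weighted}; a compactness
#' measure of the selected atoms.
#'
#' @param traj a \code{vd_trajectory}
#' @param sel atom index vector (default: all atoms)
#' @param mass_weighted use atomic masses as weights
#' @return a \code{vd_series} in Angstrom (single value per frame)
#' @export
radius_of_gyration <- function(traj, sel = seq_len(n_atoms(traj)),
                               mass_weighted = FALSE) {
  if (length(sel) == 0L) vd_error("empty selection", "vardyn_empty_selection")
  w <- if (mass_weighted) element_masses(traj$topology$element[sel])
       else rep(1, length(sel))
  wn <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- matrix(traj$coords[k, sel, ], ncol = 3L)
    cm <- colSums(fr * wn)
    sqrt(sum(wn * rowSums(sweep(fr, 2, cm)^2)))
  }, numeric(1))
  series_summary(vals, times = traj$times, unit = "A")
}

# Deterministic quasi-uniform unit sphere points (Fibonacci spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' For each atom, \code{n_points} quasi-uniform points are placed on its
#' solvent-expanded sphere (radius + probe); the accessible fraction of points
#' not buried inside any neighbour's expanded sphere, times the sphere area,
#' is the atom's SASA.
#'
#' @param frame N x 3 coordinate matrix (Angstrom)
#' @param radii per-atom van der Waals radii (Angstrom), all > 0
#' @param probe probe radius (default 1.4 Angstrom, water)
#' @param n_points sphere points per atom (default 960; minimum 32)
#' @return list with \code{per_atom} (Angstrom^2) and \code{total}
#' @export
sasa_frame <- function(frame, radii, probe = 1.4, n_points = 960L) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (length(radii) != n || any(radii <= 0)) {
    vd_error("radii must be positive, one per atom", "vardyn_value_error")
  }
  if (n_points < 32L) vd_error("n_points must be >= 32 for usable accuracy",
                               "vardyn_value_error")
  pts <- sphere_points(n_points)
  rexp <- radii + probe
  dmat <- as.matrix(stats::dist(frame))
  per_atom <- numeric(n)
  tol <- 1e-6
  for (i in seq_len(n)) {
    nbr <- which(dmat[i, ] < rexp[i] + rexp & seq_len(n) != i)
    sp <- sweep(pts * rexp[i], 2, frame[i, ], `+`)
    # weight 1 if exposed; points lying exactly on m coincident expanded
    # surfaces are split equally (weight 1/m) so overlapping identical atoms
    # share one sphere's area
    w <- rep(1, n_points)
    ties <- rep(1L, n_points)
    for (j in nbr) {
      dj <- sqrt(rowSums(sweep(sp, 2, frame[j, ])^2))
      w[dj < rexp[j] - tol] <- 0
      ties <- ties + (abs(dj - rexp[j]) <= tol)
    }
    per_atom[i] <- sum(w / ties) / n_points * 4 * pi * rexp[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Per-frame total SASA series over a trajectory
#'
#' @param traj a \code{vd_trajectory}
#' @param sel atom index vector (default: all atoms)
#' @param probe probe radius (Angstrom)
#' @param n_points sphere points per atom
#' @param unit \code{"A2"} (default) or \code{"nm2"}
#' @return a \code{vd_series}
#' @export
sasa_series <- function(traj, sel = seq_len(n_atoms(traj)), probe = 1.4,
                        n_points = 960L, unit = "A2") {
  radii <- element_radii(traj$topology$element[sel])
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    sasa_frame(matrix(traj$coords[k, sel, ], ncol = 3L), radii,
               probe = probe, n_points = n_points)$total
  }, numeric(1))
  if (unit == "nm2") vals <- vals / 100
  series_summary(vals, times = traj$times, unit = unit)
}

# Iteratively superpose all frames onto their mean structure over `sel`
# until the mean converges; returns the superposed sub-coordinates (T x n x 3
# over the selection) and the converged mean.
converged_mean_fit <- function(traj, sel, tol = 1e-7, max_iter = 50L) {
  sub <- traj$coords[, sel, , drop = FALSE]
  mref <- matrix(sub[1, , ], ncol = 3L)
  for (it in seq_len(max_iter)) {
    fitted <- superpose_frames(sub, mref)
    newm <- apply(fitted, c(2, 3), mean)
    delta <- sqrt(mean((newm - mref)^2))
    mref <- newm
    sub <- fitted
    if (delta < tol) break
  }
  list(coords = sub, mean = mref)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are first superposed onto the iteratively converged mean structure
#' over the selection; \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2
#' \rangle}}. Reported at Calpha atoms for per-residue flexibility profiles.
#'
#' @param traj a \code{vd_trajectory} with >= 2 frames
#' @param sel atom index vector (default: Calpha atoms)
#' @param superpose superpose frames onto the converged mean first (default
#'   \code{TRUE}). The rigid-body fit absorbs six degrees of freedom of
#'   apparent motion, deflating RMSF by roughly \code{sqrt(1 - 2/N)} for
#'   isotropic fluctuation of N atoms; disable for frames already in a common
#'   reference frame.
#' @return numeric vector of per-atom RMSF (Angstrom), named by residue number
#' @export
rmsf <- function(traj, sel = select_atoms(traj, "name CA"),
                 superpose = TRUE) {
  if (n_frames(traj) < 2L) vd_error("RMSF needs >= 2 frames",
                                    "vardyn_value_error")
  cf <- if (superpose) converged_mean_fit(traj, sel) else {
    sub <- traj$coords[, sel, , drop = FALSE]
    list(coords = sub, mean = apply(sub, c(2, 3), mean))
  }
  dev2 <- sweep(cf$coords, c(2, 3), cf$mean)
  # dev2 is T x n x 3; per-atom mean over frames of the squared norm
  out <- sqrt(colMeans(apply(dev2^2, c(1, 2), sum)))
  names(out) <- traj$topology$resid[sel]
  out
}

#' Convert RMSF to crystallographic B-factor
#'
#' \eqn{B = (8\pi^2/3) \cdot RMSF^2} (Angstrom^2), the temperature-factor form
#' used for putty representations of flexibility.
#'
#' @param rmsf non-negative RMSF values (Angstrom)
#' @return B-factors (Angstrom^2)
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) vd_error("RMSF must be non-negative",
                              "vardyn_value_error")
  (8 * pi^2 / 3) * rmsf^2
}
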