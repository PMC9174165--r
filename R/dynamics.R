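# Correlated-motion and essential-dynamics analysis.
#
# All operations work on Calpha (or other selected) coordinates after
# least-squares superposition onto the iteratively converged mean structure,
# which removes rigid-body motion that would otherwise inflate correlations.
# Coordinate vectors are atom-major (x1, y1, z1, x2, ...).

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of per-atom displacement vectors,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#' {(\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle)^{1/2}}}
#' with \eqn{\Delta r_i = r_i - \langle r_i \rangle} after superposition.
#' +1 is fully in-phase motion, -1 fully anti-phase. Atoms with zero variance
#' get \code{NA} rows/columns rather than a fabricated 0.
#'
#' @param traj a \code{vd_trajectory} with >= 2 frames
#' @param sel atom index vector (default: Calpha atoms)
#' @param superpose superpose frames onto the converged mean first (default
#'   \code{TRUE}; disable only for pre-fitted coordinates)
#' @return object of class \code{vd_dccm}: list with \code{residue_ids} and
#'   the R x R matrix \code{c}
#' @export
dccm <- function(traj, sel = select_atoms(traj, "name CA"), superpose = TRUE) {
  if (n_frames(traj) < 2L) vd_error("DCCM needs >= 2 frames",
                                    "vardyn_value_error")
  sub <- if (superpose) converged_mean_fit(traj, sel)$coords
         else traj$coords[, sel, , drop = FALSE]
  Tn <- dim(sub)[1]; n <- dim(sub)[2]
  # T x 3n displacement matrix, atom-major columns
  X <- matrix(0, Tn, 3L * n)
  for (k in 1:3) X[, seq(k, 3L * n, by = 3L)] <- sub[, , k]
  X <- sweep(X, 2, colMeans(X))
  C3 <- crossprod(X) / (Tn - 1L)
  num <- matrix(0, n, n)
  for (k in 1:3) {
    ik <- seq(k, 3L * n, by = 3L)
    num <- num + C3[ik, ik]
  }
  v <- diag(num)
  cmat <- num / sqrt(outer(v, v))
  cmat[v < 1e-12, ] <- NA_real_
  cmat[, v < 1e-12] <- NA_real_
  ok <- which(v >= 1e-12)
  cmat[cbind(ok, ok)] <- 1
  rid <- traj$topology$resid[sel]
  dimnames(cmat) <- list(rid, rid)
  structure(list(residue_ids = rid, c = cmat), class = "vd_dccm")
}

#' Extract strong correlation edges from a DCCM
#'
#' Off-diagonal residue pairs with \code{|c| >= threshold}, sorted by
#' descending \code{|c|}; the list form used to draw correlation lines on a
#' structure.
#'
#' @param d a \code{vd_dccm}
#' @param threshold absolute-correlation cutoff
#' @return data.frame with columns \code{res_i}, \code{res_j}, \code{c}
#' @export
dccm_edges <- function(d, threshold) {
  cmat <- d$c
  n <- nrow(cmat)
  ij <- which(upper.tri(cmat) & !is.na(cmat) & abs(cmat) >= threshold,
              arr.ind = TRUE)
  out <- data.frame(res_i = d$residue_ids[ij[, 1]],
                    res_j = d$residue_ids[ij[, 2]],
                    c = cmat[ij])
  out[order(-abs(out$c)), , drop = FALSE]
}

#' Essential-dynamics principal component analysis
#'
#' Diagonalises the positional covariance matrix of superposed coordinates
#' over the selection. Eigenvalues are in Angstrom^2 and sum to the trace, the
#' total positional variance of the ensemble; projections are the centred
#' coordinates on each eigenvector. Eigenvector signs are fixed by making each
#' vector's largest-magnitude component positive so porcupine orientations are
#' reproducible.
#'
#' @param traj a \code{vd_trajectory} with >= 2 frames
#' @param sel atom index vector (default: Calpha atoms)
#' @param superpose superpose frames onto the converged mean first
#' @return object of class \code{vd_pca}: \code{mean_structure} (n x 3),
#'   \code{eigenvectors} (3n x M orthonormal, atom-major), \code{eigenvalues}
#'   (descending, Angstrom^2), \code{projections} (T x M, Angstrom),
#'   \code{trace} (Angstrom^2), \code{residue_ids}
#' @export
pca_traj <- function(traj, sel = select_atoms(traj, "name CA"),
                     superpose = TRUE) {
  Tn <- n_frames(traj)
  if (Tn < 2L) vd_error("PCA needs >= 2 frames", "vardyn_value_error")
  n <- length(sel)
  if (Tn <= 3L * n) {
    warning("fewer frames than coordinate dimensions; ",
            "covariance is rank-deficient")
  }
  cf <- if (superpose) converged_mean_fit(traj, sel)
        else list(coords = traj$coords[, sel, , drop = FALSE],
                  mean = apply(traj$coords[, sel, , drop = FALSE],
                               c(2, 3), mean))
  X <- matrix(0, Tn, 3L * n)
  for (k in 1:3) X[, seq(k, 3L * n, by = 3L)] <- cf$coords[, , k]
  X <- sweep(X, 2, colMeans(X))
  covm <- crossprod(X) / (Tn - 1L)
  es <- eigen(covm, symmetric = TRUE)
  vecs <- es$vectors
  # deterministic sign: largest-magnitude component positive
  for (m in seq_len(ncol(vecs))) {
    comp <- vecs[which.max(abs(vecs[, m])), m]
    if (comp < 0) vecs[, m] <- -vecs[, m]
  }
  structure(list(mean_structure = cf$mean,
                 eigenvectors = vecs,
                 eigenvalues = pmax(es$values, 0),
                 projections = X %*% vecs,
                 trace = sum(pmax(es$values, 0)),
                 residue_ids = traj$topology$resid[sel]),
            class = "vd_pca")
}

#' Root-mean-square inner product between two essential subspaces
#'
#' \deqn{RMSIP = \sqrt{\frac{1}{n} \sum_{i=1}^{n} \sum_{j=1}^{n}
#' (v_i^a \cdot v_j^b)^2}} over the first \code{n_modes} eigenvectors of each
#' decomposition; 1 for identical subspaces, 0 for orthogonal ones. The
#' conventional comparisons use the first ten (heatmap) and first three
#' (summary) components.
#'
#' @param a,b \code{vd_pca} objects over the same 3N coordinate space
#' @param n_modes number of leading modes to compare (default 10)
#' @return scalar in [0, 1]
#' @export
rmsip <- function(a, b, n_modes = 10L) {
  if (nrow(a$eigenvectors) != nrow(b$eigenvectors)) {
    vd_error("subspaces have different coordinate dimensions",
             "vardyn_value_error")
  }
  if (n_modes > ncol(a$eigenvectors) || n_modes > ncol(b$eigenvectors)) {
    vd_error("n_modes exceeds available modes", "vardyn_value_error")
  }
  A <- a$eigenvectors[, seq_len(n_modes), drop = FALSE]
  B <- b$eigenvectors[, seq_len(n_modes), drop = FALSE]
  sqrt(sum((t(A) %*% B)^2) / n_modes)
}

#' Cosine content of a principal-component projection
#'
#' Overlap of the projection with the half-period cosine
#' \eqn{\cos(i \pi t / T)}:
#' \deqn{c_i = \frac{2}{T}\left(\sum_t \cos(i\pi t/T) p(t)\right)^2 /
#' \sum_t p(t)^2} (discrete form, \eqn{t = 0..T-1}). Values near 1 indicate
#' random-diffusion-like, unconverged sampling; a value below 0.1 is the
#' conventional convergence criterion.
#'
#' @param projection per-frame projection of one mode (length >= 4)
#' @param mode_index cosine period index i (default 1)
#' @return scalar in [0, 1], \code{NA} for a zero-norm projection
#' @export
cosine_content <- function(projection, mode_index = 1L) {
  p <- as.numeric(projection)
  Tn <- length(p)
  if (Tn < 4L) vd_error("projection too short", "vardyn_value_error")
  denom <- sum(p^2)
  if (denom < 1e-300) return(NA_real_)
  t <- seq_len(Tn) - 1L
  num <- sum(cos(mode_index * pi * t / Tn) * p)
  (2 / Tn) * num^2 / denom
}

#' Convergence label from cosine content
#'
#' @param cc cosine-content value(s)
#' @param limit convergence threshold (default 0.1)
#' @return logical: \code{TRUE} where sampling is deemed convergent
#' @export
is_convergent <- function(cc, limit = 0.1) !is.na(cc) & cc < limit

#' Porcupine vectors for one principal mode
#'
#' Base points are the mean structure; tips displace each atom along its
#' eigenvector component scaled by \code{scale}, the geometry used for
#' porcupine-plot rendering.
#'
#' @param p a \code{vd_pca}
#' @param mode mode number
#' @param scale displacement scale (Angstrom per unit eigenvector)
#' @return list with \code{base} and \code{tip} (n x 3 matrices, Angstrom)
#' @export
porcupine <- function(p, mode = 1L, scale = 1) {
  v <- p$eigenvectors[, mode]
  n <- nrow(p$mean_structure)
  disp <- matrix(v, ncol = 3L, byrow = TRUE)  # atom-major triples
  list(base = p$mean_structure, tip = p$mean_structure + scale * disp)
}

#' Per-residue fluctuation amplitude of one mode
#'
#' The norm of each residue's eigenvector triple times the square root of the
#' eigenvalue, i.e. the RMS displacement (Angstrom) the mode contributes per
#' residue; squared amplitudes sum to the eigenvalue.
#'
#' @param p a \code{vd_pca}
#' @param mode mode number
#' @return numeric vector named by residue number (Angstrom)
#' @export
mode_fluctuation <- function(p, mode = 1L) {
  v <- matrix(p$eigenvectors[, mode], ncol = 3L, byrow = TRUE)
  amp <- sqrt(rowSums(v^2) * p$eigenvalues[mode])
  names(amp) <- p$residue_ids
  amp
}
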