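# Secondary-structure assignment from backbone hydrogen-bond patterns
# (Kabsch-Sander model) and per-residue/per-region occupancy fractions.
#
# The electrostatic hydrogen-bond energy
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# declares a backbone C=O(i) ... H-N(j) bond when E < -0.5 kcal/mol. Amide
# hydrogens are reconstructed geometrically when absent (1.0 Angstrom from N,
# opposite the C(i-1)-N-CA bisector), so heavy-atom-only trajectories are
# supported.

KS_Q <- 0.084 * 332          # kcal/mol * Angstrom
KS_CUTOFF <- -0.5            # kcal/mol
KS_CLASH_R <- 0.5            # Angstrom; below this distances are capped

# Per-frame backbone table: one row per residue with N, CA, C, O (and H if
# present) coordinates; residues missing any heavy backbone atom are dropped.
backbone_frame <- function(frame, topology) {
  frame <- as.matrix(frame)
  key <- paste(topology$chain, topology$resid)
  res_keys <- unique(key)
  get_atom <- function(k, name) {
    i <- which(key == k & topology$atom_name == name)
    if (length(i) >= 1L) frame[i[1], ] else rep(NA_real_, 3)
  }
  bb <- lapply(res_keys, function(k) {
    list(chain = topology$chain[match(k, key)],
         resid = topology$resid[match(k, key)],
         N = get_atom(k, "N"), CA = get_atom(k, "CA"),
         C = get_atom(k, "C"), O = get_atom(k, "O"),
         H = get_atom(k, "H"))
  })
  ok <- vapply(bb, function(r)
    !anyNA(c(r$N, r$CA, r$C, r$O)), logical(1))
  bb[ok]
}

reconstruct_H <- function(bb) {
  for (i in seq_along(bb)) {
    if (!anyNA(bb[[i]]$H)) next
    if (i == 1L || bb[[i - 1L]]$chain != bb[[i]]$chain ||
        bb[[i]]$resid != bb[[i - 1L]]$resid + 1L) {
      bb[[i]]$H <- rep(NA_real_, 3)  # chain start: no amide H
      next
    }
    n <- bb[[i]]$N
    u1 <- bb[[i - 1L]]$C - n; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- bb[[i]]$CA - n; u2 <- u2 / sqrt(sum(u2^2))
    dir <- -(u1 + u2)
    dir <- dir / sqrt(sum(dir^2))
    bb[[i]]$H <- n + 1.0 * dir
  }
  bb
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic energy between the C=O group of \code{acceptor} and the N-H
#' group of \code{donor} (kcal/mol); a hydrogen bond is declared below
#' -0.5 kcal/mol. Distances under 0.5 Angstrom are treated as a clash and the
#' energy capped.
#'
#' @param donor list with \code{N} and \code{H} coordinates (length-3)
#' @param acceptor list with \code{C} and \code{O} coordinates
#' @return energy in kcal/mol (\code{Inf} if the donor has no H)
#' @export
hbond_energy <- function(donor, acceptor) {
  if (anyNA(donor$H) || anyNA(donor$N) || anyNA(acceptor$C) ||
      anyNA(acceptor$O)) return(Inf)
  d <- function(a, b) max(sqrt(sum((a - b)^2)), KS_CLASH_R)
  KS_Q * (1 / d(acceptor$O, donor$N) + 1 / d(acceptor$C, donor$H) -
            1 / d(acceptor$O, donor$H) - 1 / d(acceptor$C, donor$N))
}

# R x R logical matrix: hb[i, j] TRUE when CO of residue i accepts an H-bond
# from NH of residue j (i -> j in Kabsch-Sander notation), i != j.
hbond_matrix <- function(bb) {
  nres <- length(bb)
  hb <- matrix(FALSE, nres, nres)
  if (nres < 2L) return(hb)
  Opos <- t(vapply(bb, `[[`, numeric(3), "O"))
  Npos <- t(vapply(bb, `[[`, numeric(3), "N"))
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (abs(i - j) < 1L || i == j) next
      if (sum((Opos[i, ] - Npos[j, ])^2) > 49) next  # 7 A screen
      e <- hbond_energy(bb[[j]], bb[[i]])
      hb[i, j] <- e < KS_CUTOFF
    }
  }
  hb
}

chain_breaks <- function(bb) {
  nres <- length(bb)
  if (nres < 2L) return(logical(0))
  vapply(seq_len(nres - 1L), function(i) {
    bb[[i]]$chain != bb[[i + 1L]]$chain ||
      bb[[i + 1L]]$resid != bb[[i]]$resid + 1L ||
      sqrt(sum((bb[[i]]$C - bb[[i + 1L]]$N)^2)) > 2.5
  }, logical(1))
}

#' Assign per-residue secondary structure for one frame
#'
#' Kabsch-Sander patterns on backbone hydrogen bonds: two consecutive
#' i -> i+4 turns make an alpha-helix (H), i -> i+3 a 3-10 helix (G),
#' i -> i+5 a pi-helix (reported as other), parallel/antiparallel bridge
#' patterns make strand (E), an isolated turn is T, everything else coil (C).
#' Conflicts resolve with priority H > E > G > T. Chain breaks (C-N distance
#' > 2.5 Angstrom or non-consecutive numbering) split the assignment.
#'
#' @param frame N x 3 coordinate matrix (Angstrom)
#' @param topology matching topology data.frame
#' @return character vector of labels over \{H, G, E, T, C\} named by residue
#'   number (residues with incomplete backbones are omitted)
#' @export
assign_ss <- function(frame, topology) {
  bb <- reconstruct_H(backbone_frame(frame, topology))
  nres <- length(bb)
  labels <- rep("C", nres)
  if (nres < 3L) {
    names(labels) <- vapply(bb, `[[`, integer(1), "resid")
    return(labels)
  }
  brk <- chain_breaks(bb)
  contiguous <- function(i, j) {
    if (i > j) return(contiguous(j, i))
    i >= 1L && j <= nres && (i == j || !any(brk[i:(j - 1L)]))
  }
  hb <- hbond_matrix(bb)
  turn <- function(i, n) i >= 1L && i + n <= nres && contiguous(i, i + n) &&
    hb[i, i + n]
  isH <- isG <- isI <- isE <- isT <- rep(FALSE, nres)
  # helices: two consecutive n-turns at i-1 and i cover residues i..i+n-1
  for (i in 2:nres) {
    if (turn(i - 1L, 4L) && turn(i, 4L)) isH[i:min(i + 3L, nres)] <- TRUE
    if (turn(i - 1L, 3L) && turn(i, 3L)) isG[i:min(i + 2L, nres)] <- TRUE
    if (turn(i - 1L, 5L) && turn(i, 5L)) isI[i:min(i + 4L, nres)] <- TRUE
  }
  # bridges
  for (i in 2:(nres - 1L)) {
    for (j in 2:(nres - 1L)) {
      if (abs(i - j) < 3L) next
      if (!contiguous(i - 1L, i + 1L) || !contiguous(j - 1L, j + 1L)) next
      para <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
        (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (para || anti) isE[c(i, j)] <- TRUE
    }
  }
  # isolated turns
  for (i in seq_len(nres)) {
    for (n in 3:5) if (turn(i, n) && i + n <= nres)
      isT[(i + 1L):(i + n - 1L)] <- TRUE
  }
  labels[isT] <- "T"
  labels[isG] <- "G"
  labels[isI] <- "C"  # pi-helix folded into "other"
  labels[isE] <- "E"
  labels[isH] <- "H"
  names(labels) <- vapply(bb, `[[`, integer(1), "resid")
  labels
}

#' Secondary-structure timeline over a trajectory
#'
#' @param traj a \code{vd_trajectory} with backbone atoms
#' @return object of class \code{vd_ss_timeline}: T x R character matrix
#'   \code{labels} (columns named by residue number) and \code{residue_ids}
#' @export
ss_timeline <- function(traj) {
  rows <- lapply(seq_len(n_frames(traj)), function(k)
    assign_ss(frame_coords(traj, k), traj$topology))
  labels <- do.call(rbind, rows)
  structure(list(labels = labels,
                 residue_ids = as.integer(colnames(labels))),
            class = "vd_ss_timeline")
}

SS_CLASSES <- c("H", "G", "E", "other")

collapse_class <- function(lab) {
  ifelse(lab %in% c("H", "G", "E"), lab, "other")
}

#' Secondary-structure occupancy fractions
#'
#' Fraction of frames each residue spends in alpha-helix (H), 3-10 helix (G),
#' strand (E), or other; per-region occupancy is the mean over the region's
#' residues. Fractions per residue sum to 1.
#'
#' @param timeline a \code{vd_ss_timeline}
#' @param regions optional named list of residue-number vectors (e.g.
#'   \code{list(CDR1 = 40:47)})
#' @return list with \code{per_residue} (data.frame: resid, fracH, fracG,
#'   fracE, fracOther) and \code{per_region} (data.frame: region, class,
#'   fraction, percent), the latter \code{NULL} without regions
#' @export
ss_occupancy <- function(timeline, regions = NULL) {
  lab <- apply(timeline$labels, c(1, 2), collapse_class)
  Tn <- nrow(lab)
  frac <- sapply(SS_CLASSES, function(cl) colMeans(lab == cl))
  per_res <- data.frame(resid = timeline$residue_ids,
                        fracH = frac[, "H"], fracG = frac[, "G"],
                        fracE = frac[, "E"], fracOther = frac[, "other"],
                        row.names = NULL)
  per_region <- NULL
  if (!is.null(regions)) {
    rows <- list()
    for (rn in names(regions)) {
      sel <- per_res$resid %in% regions[[rn]]
      if (!any(sel)) vd_error(sprintf("region %s outside topology", rn),
                              "vardyn_value_error")
      for (cl in SS_CLASSES) {
        f <- mean(frac[sel, cl])
        rows[[length(rows) + 1L]] <- data.frame(region = rn, class = cl,
                                                fraction = f,
                                                percent = 100 * f)
      }
    }
    per_region <- do.call(rbind, rows)
  }
  list(per_residue = per_res, per_region = per_region)
}
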