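# Inter-loop anchor distances and inter-region contact-occupancy maps.
#
# The reference region set is the three complementarity-determining loops of
# the TREM2 Ig domain in 5UD7 numbering -- CDR1 = residues 40-47, CDR2 =
# 67-78, CDR3 = 115-120 -- with Calpha anchors His43, Leu72 and Ser116.
# A residue pair is "in contact" in a frame when the minimum heavy-atom
# distance is at or below a cutoff (4.5 Angstrom by convention); occupancy is
# the exact fraction of frames in contact, and persistent contacts are those
# whose occupancy strictly exceeds 10%.

#' Default CDR region set
#'
#' @return list with \code{regions} (named residue-number vectors) and
#'   \code{anchors} (named single residue numbers inside their regions)
#' @export
default_regions <- function() {
  rs <- list(regions = list(CDR1 = 40:47, CDR2 = 67:78, CDR3 = 115:120),
             anchors = c(CDR1 = 43L, CDR2 = 72L, CDR3 = 116L))
  validate_regions(rs)
  rs
}

validate_regions <- function(rs) {
  regs <- rs$regions
  all_res <- unlist(regs, use.names = FALSE)
  if (anyDuplicated(all_res)) vd_error("regions must not overlap",
                                       "vardyn_value_error")
  for (nm in names(rs$anchors)) {
    if (!rs$anchors[[nm]] %in% regs[[nm]]) {
      vd_error(sprintf("anchor for %s lies outside its region", nm),
               "vardyn_value_error")
    }
  }
  invisible(rs)
}

#' Per-frame Calpha-Calpha distance between two anchor residues
#'
#' @param traj a \code{vd_trajectory}
#' @param resA,resB residue numbers; both must have a Calpha atom
#' @return a \code{vd_series} (Angstrom) with mean, density and quartile
#'   summaries
#' @export
anchor_distance_series <- function(traj, resA, resB) {
  topo <- traj$topology
  ia <- which(topo$resid == resA & topo$atom_name == "CA")[1]
  ib <- which(topo$resid == resB & topo$atom_name == "CA")[1]
  if (is.na(ia) || is.na(ib)) {
    vd_error("anchor residue lacks a Calpha atom", "vardyn_value_error")
  }
  d <- sqrt(rowSums((traj$coords[, ia, , drop = FALSE] -
                       traj$coords[, ib, , drop = FALSE])^2,
                    dims = 1))
  series_summary(as.numeric(d), times = traj$times, unit = "A")
}

#' Inter-region residue contact occupancy
#'
#' For each residue pair (one residue per region), the fraction of frames in
#' which the minimum heavy-atom distance is at or below \code{cutoff}.
#' Occupancies are exact rationals k/T.
#'
#' @param traj a \code{vd_trajectory}
#' @param regionA,regionB disjoint residue-number vectors
#' @param cutoff contact distance cutoff (Angstrom, default 4.5)
#' @return object of class \code{vd_contact_map}: data.frame \code{pairs}
#'   (res_i, res_j, occupancy) plus \code{n_frames}, \code{cutoff}
#' @export
contact_occupancy <- function(traj, regionA, regionB, cutoff = 4.5) {
  if (length(intersect(regionA, regionB)) > 0L) {
    vd_error("regions must be disjoint", "vardyn_value_error")
  }
  topo <- traj$topology
  heavy <- topo$element != "H"
  idxA <- lapply(regionA, function(r) which(topo$resid == r & heavy))
  idxB <- lapply(regionB, function(r) which(topo$resid == r & heavy))
  if (all(lengths(idxA) == 0L) || all(lengths(idxB) == 0L)) {
    vd_error("empty region", "vardyn_value_error")
  }
  keepA <- lengths(idxA) > 0L; keepB <- lengths(idxB) > 0L
  regionA <- regionA[keepA]; idxA <- idxA[keepA]
  regionB <- regionB[keepB]; idxB <- idxB[keepB]
  Tn <- n_frames(traj)
  counts <- matrix(0L, length(regionA), length(regionB))
  for (k in seq_len(Tn)) {
    fr <- frame_coords(traj, k)
    for (a in seq_along(regionA)) {
      ca <- fr[idxA[[a]], , drop = FALSE]
      for (b in seq_along(regionB)) {
        cb <- fr[idxB[[b]], , drop = FALSE]
        d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * ca %*% t(cb)
        if (min(d2) <= cutoff^2) counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  # expand.grid varies res_i fastest, matching column-major as.vector(counts)
  pairs <- expand.grid(res_i = regionA, res_j = regionB)
  pairs$occupancy <- as.vector(counts) / Tn
  structure(list(pairs = pairs, n_frames = Tn, cutoff = cutoff),
            class = "vd_contact_map")
}

#' Filter a contact map by persistence
#'
#' Keeps residue pairs whose occupancy strictly exceeds \code{min_occupancy}
#' ("exceeded 10\%" -- a pair at exactly the threshold is removed).
#'
#' @param map a \code{vd_contact_map}
#' @param min_occupancy persistence threshold (default 0.10)
#' @return a filtered \code{vd_contact_map}
#' @export
filter_contacts <- function(map, min_occupancy = 0.10) {
  keep <- map$pairs$occupancy > min_occupancy
  structure(list(pairs = map$pairs[keep, , drop = FALSE],
                 n_frames = map$n_frames, cutoff = map$cutoff),
            class = "vd_contact_map")
}
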