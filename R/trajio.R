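# Trajectory container and multi-model PDB I/O.
#
# A trajectory is the T x N x 3 coordinate history (Angstrom) of a fixed
# topology, with a strictly increasing time axis in nanoseconds. Residue
# numbering is taken verbatim from the input PDB (5UD7 numbering for TREM2),
# so region definitions such as CDR1 = residues 40-47 apply unchanged.
# Coordinates are orthogonal Angstrom with no periodic box: frames are assumed
# pre-imaged, whole molecules.

vd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vardyn_error")))
}

#' Construct a trajectory
#'
#' Bundles a topology (per-atom metadata), a \code{T x N x 3} coordinate array
#' in Angstrom and a strictly increasing time axis in nanoseconds. When
#' \code{times} is omitted, frames are spaced \code{dt} ns apart starting at 0,
#' matching a 100 ps trajectory save interval by default.
#'
#' @param topology data.frame with columns \code{atom_name}, \code{element},
#'   \code{resid} (integer residue sequence number), \code{resname},
#'   \code{chain}.
#' @param coords numeric array of dimension \code{c(T, N, 3)} (Angstrom), or an
#'   \code{N x 3} matrix for a single frame.
#' @param times numeric vector of frame times in ns, strictly increasing, or
#'   \code{NULL} to use \code{dt * (0:(T-1))}.
#' @param dt frame spacing in ns used when \code{times} is \code{NULL}
#'   (default 0.1 ns).
#' @return An object of class \code{vd_trajectory}.
#' @export
trajectory <- function(topology, coords, times = NULL, dt = 0.1) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  need <- c("atom_name", "element", "resid", "resname", "chain")
  if (!all(need %in% names(topology))) {
    vd_error(paste("topology must have columns:", paste(need, collapse = ", ")),
             "vardyn_value_error")
  }
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (n_frames < 1L) vd_error("trajectory must have at least one frame",
                              "vardyn_value_error")
  if (nrow(topology) != n_atoms) {
    vd_error("coords second dimension must equal number of topology atoms",
             "vardyn_structural_mismatch")
  }
  if (is.null(times)) times <- dt * (seq_len(n_frames) - 1L)
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    vd_error("times must be strictly increasing with one entry per frame",
             "vardyn_value_error")
  }
  topology <- as.data.frame(topology)[, need]
  rownames(topology) <- NULL
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times)),
            class = "vd_trajectory")
}

#' @export
print.vd_trajectory <- function(x, ...) {
  cat(sprintf("<vd_trajectory> %d frames, %d atoms, %.4g-%.4g ns\n",
              n_frames(x), n_atoms(x), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{vd_trajectory}
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Number of atoms in a trajectory
#' @param traj a \code{vd_trajectory}
#' @return integer atom count
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj a \code{vd_trajectory}
#' @param i frame index (1-based)
#' @return N x 3 numeric matrix (Angstrom)
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) vd_error("frame index out of range",
                                             "vardyn_value_error")
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

topologies_identical <- function(a, b) {
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}

# ---- multi-model PDB ------------------------------------------------------

parse_atom_line <- function(line, lineno) {
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(xyz) || is.na(resid)) {
    vd_error(sprintf("unparseable ATOM record at line %d", lineno),
             "vardyn_format_error")
  }
  list(atom_name = trimws(substr(line, 13, 16)),
       altloc = substr(line, 17, 17),
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22),
       resid = resid,
       icode = substr(line, 27, 27),
       xyz = xyz,
       element = trimws(substr(line, 77, 78)))
}

guess_element <- function(atom_name) {
  # PDB columns 13-14 hold the element for standard protein atoms; fall back
  # to the first alphabetic character of the atom name.
  a <- sub("^[0-9]*", "", atom_name)
  first <- toupper(substr(a, 1, 1))
  if (first %in% c("C", "N", "O", "S", "H", "P")) first else first
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each \code{MODEL}/\code{ENDMDL} block becomes one frame; a file without
#' \code{MODEL} records is read as a single frame. Only \code{ATOM} records
#' with alternate-location indicator \code{' '} or \code{'A'} are kept;
#' insertion codes are rejected so that residue sequence numbers are
#' unambiguous keys for region definitions. All models must contain identical
#' atom records.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ns assigned to the frames (default 0.1).
#' @return A \code{vd_trajectory}.
#' @export
read_multi_model_pdb <- function(path, dt = 0.1) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_model <- startsWith(rec, "MODEL")
  is_atom <- rec == "ATOM  "
  if (!any(is_atom)) vd_error("no ATOM records in file", "vardyn_format_error")
  if (any(is_model)) {
    starts <- which(is_model)
    ends <- c(starts[-1] - 1L, length(lines))
    blocks <- Map(function(s, e) s:e, starts, ends)
  } else {
    blocks <- list(seq_along(lines))
  }
  frames <- vector("list", length(blocks))
  topo <- NULL
  meta_key <- NULL
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]][is_atom[blocks[[k]]]]
    atoms <- lapply(idx, function(i) parse_atom_line(lines[i], i))
    keep <- vapply(atoms, function(a) a$altloc %in% c(" ", "A"), logical(1))
    atoms <- atoms[keep]
    if (length(atoms) == 0L) {
      vd_error(sprintf("model %d has no usable ATOM records", k),
               "vardyn_structural_mismatch")
    }
    if (any(vapply(atoms, function(a) a$icode != " ", logical(1)))) {
      vd_error("insertion codes are not supported", "vardyn_format_error")
    }
    key <- vapply(atoms, function(a)
      paste(a$atom_name, a$resname, a$chain, a$resid), character(1))
    if (is.null(meta_key)) {
      meta_key <- key
      el <- vapply(atoms, function(a)
        if (nzchar(a$element)) a$element else guess_element(a$atom_name),
        character(1))
      topo <- data.frame(
        atom_name = vapply(atoms, `[[`, character(1), "atom_name"),
        element = el,
        resid = vapply(atoms, `[[`, integer(1), "resid"),
        resname = vapply(atoms, `[[`, character(1), "resname"),
        chain = vapply(atoms, `[[`, character(1), "chain"),
        stringsAsFactors = FALSE)
    } else if (length(key) != length(meta_key) || any(key != meta_key)) {
      vd_error(sprintf(
        "model %d atom records do not match model 1 (%d vs %d atoms)",
        k, length(key), length(meta_key)), "vardyn_structural_mismatch")
    }
    frames[[k]] <- t(vapply(atoms, `[[`, numeric(3), "xyz"))
  }
  coords <- array(0, dim = c(length(frames), nrow(topo), 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  trajectory(topo, coords, dt = dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written in the fixed \code{\%8.3f} PDB columns; values that
#' do not fit the field raise an error rather than being truncated silently.
#'
#' @param traj a \code{vd_trajectory}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_multi_model_pdb <- function(traj, path) {
  if (!inherits(traj, "vd_trajectory")) vd_error("not a trajectory",
                                                 "vardyn_value_error")
  if (!all(is.finite(traj$coords))) {
    vd_error("non-finite coordinates cannot be written", "vardyn_value_error")
  }
  if (any(traj$coords > 9999.999 | traj$coords < -999.999)) {
    vd_error("coordinate overflows fixed-width PDB field", "vardyn_value_error")
  }
  topo <- traj$topology
  name_field <- ifelse(nchar(topo$atom_name) < 4L,
                       sprintf(" %-3s", topo$atom_name),
                       topo$atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(traj, k)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(topo)), name_field, topo$resname, topo$chain, topo$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, topo$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- atom selection -------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")

select_term <- function(topology, term) {
  term <- trimws(term)
  if (term == "all") return(rep(TRUE, nrow(topology)))
  if (term == "backbone") return(topology$atom_name %in% BACKBONE_NAMES)
  m <- regmatches(term, regexec("^name ([A-Za-z0-9',]+)$", term))[[1]]
  if (length(m) == 2L) {
    return(topology$atom_name %in% strsplit(m[2], ",")[[1]])
  }
  m <- regmatches(term, regexec("^resid ([0-9]+)-([0-9]+)$", term))[[1]]
  if (length(m) == 3L) {
    return(topology$resid >= as.integer(m[2]) &
             topology$resid <= as.integer(m[3]))
  }
  m <- regmatches(term, regexec("^resid ([0-9,]+)$", term))[[1]]
  if (length(m) == 2L) {
    return(topology$resid %in% as.integer(strsplit(m[2], ",")[[1]]))
  }
  m <- regmatches(term, regexec("^chain ([A-Za-z0-9])$", term))[[1]]
  if (length(m) == 2L) return(topology$chain == m[2])
  vd_error(sprintf("unknown selection token: '%s'", term),
           "vardyn_parse_error")
}

#' Select atoms by a small expression grammar
#'
#' Supported terms: \code{name CA} (comma lists allowed), \code{backbone}
#' (N, CA, C, O), \code{resid 40-47}, \code{resid 40,43,47},
#' \code{chain A}, \code{all}; terms combine with \code{and} / \code{or}
#' (\code{and} binds tighter). The result is a deterministic, sorted,
#' duplicate-free index vector; an empty result is an error because downstream
#' statistics divide by selection sizes.
#'
#' @param traj a \code{vd_trajectory} (or bare topology data.frame)
#' @param expr selection expression string
#' @return sorted integer vector of 1-based atom indices with attribute
#'   \code{label} set to \code{expr}.
#' @export
select_atoms <- function(traj, expr) {
  topology <- if (inherits(traj, "vd_trajectory")) traj$topology else traj
  ors <- strsplit(expr, "\\s+or\\s+")[[1]]
  mask <- rep(FALSE, nrow(topology))
  for (clause in ors) {
    ands <- strsplit(clause, "\\s+and\\s+")[[1]]
    cm <- rep(TRUE, nrow(topology))
    for (term in ands) cm <- cm & select_term(topology, term)
    mask <- mask | cm
  }
  idx <- which(mask)
  if (length(idx) == 0L) {
    vd_error(sprintf("selection '%s' matches no atoms", expr),
             "vardyn_empty_selection")
  }
  structure(idx, label = expr)
}

# ---- slicing and concatenation --------------------------------------------

#' Extract frames within a time window
#'
#' Keeps frames with \code{t_start <= t <= t_stop}, preserving their original
#' timestamps. Used to discard pre-equilibration frames, e.g. keeping the last
#' 300 ns of a 500 ns replica.
#'
#' @param traj a \code{vd_trajectory}
#' @param t_start,t_stop window bounds in ns, \code{t_start < t_stop}
#' @return A \code{vd_trajectory} restricted to the window.
#' @export
slice_time <- function(traj, t_start, t_stop) {
  if (t_start >= t_stop) vd_error("t_start must be < t_stop",
                                  "vardyn_value_error")
  keep <- traj$times >= t_start & traj$times <= t_stop
  if (!any(keep)) vd_error("time slice contains no frames",
                           "vardyn_empty_slice")
  trajectory(traj$topology,
             traj$coords[keep, , , drop = FALSE],
             times = traj$times[keep])
}

#' Concatenate replica trajectories onto one time axis
#'
#' Frames are appended in list order and times re-indexed with a cumulative
#' offset so the combined axis is strictly increasing (three 300 ns slices
#' become one 900 ns sub-trajectory). The original (replica, time) of each
#' frame is kept in the \code{provenance} attribute.
#'
#' @param trajs list of \code{vd_trajectory} objects with identical topologies
#' @return A single concatenated \code{vd_trajectory}.
#' @export
concat_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  topo <- trajs[[1]]$topology
  for (k in seq_along(trajs)) {
    if (!topologies_identical(topo, trajs[[k]]$topology)) {
      vd_error(sprintf("replica %d topology differs from replica 1", k),
               "vardyn_structural_mismatch")
    }
  }
  total <- sum(vapply(trajs, n_frames, integer(1)))
  coords <- array(0, dim = c(total, nrow(topo), 3L))
  times <- numeric(total)
  prov_rep <- integer(total)
  prov_time <- numeric(total)
  offset <- 0
  pos <- 0L
  for (k in seq_along(trajs)) {
    tk <- trajs[[k]]
    Tk <- n_frames(tk)
    dtk <- if (Tk > 1L) tk$times[2] - tk$times[1] else 0.1
    rows <- pos + seq_len(Tk)
    coords[rows, , ] <- tk$coords
    times[rows] <- offset + (tk$times - tk$times[1]) +
      (if (k > 1L) dtk else 0)
    prov_rep[rows] <- k
    prov_time[rows] <- tk$times
    offset <- times[rows[Tk]]
    pos <- pos + Tk
  }
  out <- trajectory(topo, coords, times = times)
  attr(out, "provenance") <- data.frame(replica = prov_rep,
                                        orig_time_ns = prov_time)
  out
}
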