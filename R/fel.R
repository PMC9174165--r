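# Free-energy landscape by Boltzmann inversion of a 2-D descriptor histogram.
#
# Over the (RMSD, Rg) plane the per-bin free energy is
#   G_i = -k_B * T * ln(N_i / N_max)
# at T = 300 K, so the most occupied bin sits at exactly G = 0 and empty bins
# are +Inf (masked), never a finite cap. k_B*T at 300 K = 0.59616 kcal/mol.

KB_KCAL <- 0.0019872041  # kcal/mol/K

#' Free-energy landscape over a 2-D descriptor plane
#'
#' Builds a 2-D histogram of the paired per-frame series (by default RMSD vs
#' radius of gyration) over data-driven ranges with 1\% padding and Boltzmann-
#' inverts the counts. Energies are in units of kT by default, or kcal/mol.
#'
#' @param x,y equal-length per-frame series (Angstrom); conventionally RMSD
#'   and Rg
#' @param bins number of bins per axis (default 100; series must be at least
#'   as long)
#' @param temperature_K temperature for the kcal/mol scale (default 300)
#' @param units \code{"kT"} (default) or \code{"kcal"}
#' @return object of class \code{vd_fel}: \code{x_edges}, \code{y_edges},
#'   \code{counts} (bins x bins), \code{g} (free energy; +Inf for empty bins),
#'   \code{temperature_K}, \code{units}, \code{bin_index} (per-frame bin of
#'   each input point)
#' @export
fel_surface <- function(x, y, bins = 100L, temperature_K = 300,
                        units = "kT") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) vd_error("series lengths differ",
                                       "vardyn_value_error")
  if (length(x) < bins) vd_error("need at least `bins` frames",
                                 "vardyn_value_error")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    vd_error("zero-variance descriptor axis", "vardyn_degenerate_axis")
  }
  pad <- function(r) r + c(-1, 1) * 0.01 * diff(r)
  rx <- pad(range(x)); ry <- pad(range(y))
  x_edges <- seq(rx[1], rx[2], length.out = bins + 1L)
  y_edges <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L),
             bins)
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L),
             bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  kT <- if (units == "kcal") KB_KCAL * temperature_K else 1
  g <- matrix(Inf, bins, bins)
  occ <- counts > 0L
  g[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 g = g, temperature_K = temperature_K, units = units,
                 bin_index = cbind(ix, iy)),
            class = "vd_fel")
}

#' Representative lowest-energy conformer
#'
#' Among the frames falling in the global-minimum (most occupied) bin, returns
#' the frame nearest the bin centre in normalised bin units, with ties broken
#' by earliest time.
#'
#' @param grid a \code{vd_fel} built from the same series
#' @param x,y the series the grid was built from
#' @param times per-frame times (ns)
#' @return list with \code{frame_index} and \code{time_ns}
#' @export
lowest_energy_frame <- function(grid, x, y, times = seq_along(x)) {
  if (all(grid$counts == 0L)) vd_error("empty grid", "vardyn_value_error")
  modal <- which(grid$counts == max(grid$counts), arr.ind = TRUE)[1, ]
  inbin <- which(grid$bin_index[, 1] == modal[1] &
                   grid$bin_index[, 2] == modal[2])
  cx <- (grid$x_edges[modal[1]] + grid$x_edges[modal[1] + 1L]) / 2
  cy <- (grid$y_edges[modal[2]] + grid$y_edges[modal[2] + 1L]) / 2
  wx <- diff(grid$x_edges[1:2]); wy <- diff(grid$y_edges[1:2])
  d2 <- ((x[inbin] - cx) / wx)^2 + ((y[inbin] - cy) / wy)^2
  ord <- order(d2, times[inbin])
  best <- inbin[ord[1]]
  list(frame_index = best, time_ns = times[best])
}

#' Long-form export of a free-energy landscape
#'
#' Occupied (finite-energy) bins only, one row per bin with bin-centre
#' coordinates, sorted by free energy ascending -- the table behind 3-D
#' surface renderings.
#'
#' @param grid a \code{vd_fel}
#' @return data.frame with columns \code{x}, \code{y}, \code{g}, \code{count}
#' @export
fel_3d_export <- function(grid) {
  occ <- which(is.finite(grid$g), arr.ind = TRUE)
  xc <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2
  out <- data.frame(x = xc[occ[, 1]], y = yc[occ[, 2]],
                    g = grid$g[occ], count = grid$counts[occ])
  out[order(out$g, out$x, out$y), , drop = FALSE]
}
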