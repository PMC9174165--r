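# Full-study orchestration: per-replica equilibration trimming, replica
# concatenation, every analysis stage, and a machine-readable report.
#
# The workflow mirrors the reference study: three replicas per variant are
# trimmed to their equilibrated tails (the final 60% by default, generalising
# "keep the last 300 ns of each 500 ns run"), concatenated onto one time axis,
# then passed through descriptors, correlated-motion and essential-dynamics
# analysis, secondary-structure occupancy, inter-loop distances/contacts and
# the free-energy landscape. Sampling convergence is gated on cosine content
# < 0.1 of the first three principal components -- a warning, not a failure,
# matching its use as a diagnostic.

#' Default pipeline configuration
#'
#' @param variants named list; each element a character vector of replica
#'   multi-model PDB paths (first variant is the baseline, conventionally the
#'   wild-type)
#' @param output_dir directory for report files (created if needed)
#' @return config list understood by \code{\link{run_full_analysis}}
#' @export
default_config <- function(variants, output_dir = tempfile("vardyn_run_")) {
  list(variants = variants,
       dt_ns = 0.1,
       equilibration_keep_fraction = 0.6,
       regions = default_regions(),
       consensus_threshold = 15L,
       contact_cutoff = 4.5,
       min_contact_occupancy = 0.10,
       fel_bins = 100L,
       temperature_K = 300,
       rmsip_modes = c(3L, 10L),
       cosine_limit = 0.1,
       sasa_n_points = 240L,
       output_dir = output_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror \code{\link{default_config}}; \code{regions} may be
#' given as named \code{[first, last]} residue ranges with an \code{anchors}
#' map.
#'
#' @param path YAML file path
#' @return config list
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config(y$variants,
                        output_dir = y$output_dir %||% tempfile("vardyn_run_"))
  for (key in intersect(names(y), names(cfg))) cfg[[key]] <- y[[key]]
  if (!is.null(y$regions)) {
    regs <- lapply(y$regions, function(r) seq(r[[1]], r[[2]]))
    anchors <- unlist(y$anchors)
    cfg$regions <- validate_regions(list(regions = regs, anchors = anchors))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Re-raise any stage error with the stage name and variant prepended,
# preserving the condition class so callers can still dispatch on it.
run_stage <- function(stage, variant, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(errorCondition(
      sprintf("[%s / stage %s] %s", variant, stage, conditionMessage(e)),
      class = setdiff(class(e), c("error", "condition"))))
  })
}

analyse_variant <- function(name, replica_paths, cfg) {
  trajs <- run_stage("trajio.read", name,
                     lapply(replica_paths, read_multi_model_pdb,
                            dt = cfg$dt_ns))
  keep <- cfg$equilibration_keep_fraction
  sliced <- lapply(trajs, function(tr) {
    t0 <- tr$times[1]; t1 <- tr$times[length(tr$times)]
    slice_time(tr, t1 - keep * (t1 - t0), t1)
  })
  # per-replica sampling-convergence gate on the first three PCs
  cosine <- lapply(seq_along(sliced), function(i) {
    p <- pca_traj(sliced[[i]])
    cc <- vapply(1:3, function(m) cosine_content(p$projections[, m], m),
                 numeric(1))
    data.frame(variant = name, replica = i, pc = 1:3, cosine_content = cc,
               convergent = is_convergent(cc, cfg$cosine_limit))
  })
  cosine <- do.call(rbind, cosine)
  if (any(!cosine$convergent)) {
    warning(sprintf("%s: cosine content >= %.2f on some components; %s",
                    name, cfg$cosine_limit,
                    "sampling may resemble random diffusion"))
  }
  traj <- run_stage("trajio.concat", name, concat_trajectories(sliced))
  ca <- select_atoms(traj, "name CA")
  bb <- tryCatch(select_atoms(traj, "backbone"),
                 vardyn_empty_selection = function(e) ca)
  rmsd <- rmsd_series(traj, sel = bb)
  rg <- radius_of_gyration(traj)
  sasa <- sasa_series(traj, n_points = cfg$sasa_n_points)
  flex <- rmsf(traj, sel = ca)
  bfac <- rmsf_to_bfactor(flex)
  dc <- dccm(traj, sel = ca)
  pc <- pca_traj(traj, sel = ca)
  has_bb <- all(c("N", "C", "O") %in% traj$topology$atom_name)
  ss <- if (has_bb) ss_occupancy(ss_timeline(traj), cfg$regions$regions)
        else NULL
  anchors <- cfg$regions$anchors
  present <- vapply(anchors, function(r)
    any(traj$topology$resid == r & traj$topology$atom_name == "CA"),
    logical(1))
  dist_tables <- NULL
  contacts <- NULL
  if (all(present)) {
    pairs <- utils::combn(names(anchors), 2, simplify = FALSE)
    dist_tables <- lapply(pairs, function(pr) {
      s <- anchor_distance_series(traj, anchors[[pr[1]]], anchors[[pr[2]]])
      data.frame(variant = name, pair = paste(pr, collapse = "-"),
                 mean_A = s$mean, median_A = s$median,
                 q25 = s$quartiles[1], q75 = s$quartiles[2])
    })
    dist_tables <- do.call(rbind, dist_tables)
    rpairs <- utils::combn(names(cfg$regions$regions), 2, simplify = FALSE)
    contacts <- lapply(rpairs, function(pr) {
      cm <- contact_occupancy(traj, cfg$regions$regions[[pr[1]]],
                              cfg$regions$regions[[pr[2]]],
                              cutoff = cfg$contact_cutoff)
      cm <- filter_contacts(cm, cfg$min_contact_occupancy)
      if (nrow(cm$pairs) > 0L) {
        cbind(variant = name, regions = paste(pr, collapse = "-"), cm$pairs)
      } else NULL
    })
    contacts <- do.call(rbind, contacts)
  }
  grid <- fel_surface(rmsd$values, rg$values, bins = cfg$fel_bins,
                      temperature_K = cfg$temperature_K)
  rep_frame <- lowest_energy_frame(grid, rmsd$values, rg$values, traj$times)
  list(name = name, traj = traj, cosine = cosine,
       rmsd = rmsd, rg = rg, sasa = sasa, rmsf = flex, bfactor = bfac,
       dccm = dc, pca = pc, ss = ss, distances = dist_tables,
       contacts = contacts, fel = grid, representative = rep_frame)
}

#' Run the full variant-comparison workflow
#'
#' Executes every stage for each variant (see file-level notes for the order),
#' computes the cross-variant RMSIP matrix, and writes CSV/JSON artifacts plus
#' a manifest (config hash, seed-free stage determinism) under
#' \code{config$output_dir}.
#'
#' @param config list from \code{\link{default_config}} or
#'   \code{\link{read_config}}
#' @return report list (class \code{vd_report}) with one entry per variant
#'   plus \code{rmsip}, \code{cosine}, \code{manifest}
#' @export
run_full_analysis <- function(config) {
  stopifnot(length(config$variants) >= 1L)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- lapply(names(config$variants), function(nm)
    analyse_variant(nm, config$variants[[nm]], config))
  names(results) <- names(config$variants)
  vs <- names(results)
  rmsip_tabs <- lapply(config$rmsip_modes, function(nm_modes) {
    m <- matrix(NA_real_, length(vs), length(vs), dimnames = list(vs, vs))
    for (i in seq_along(vs)) for (j in seq_along(vs)) {
      m[i, j] <- rmsip(results[[i]]$pca, results[[j]]$pca,
                       n_modes = nm_modes)
    }
    m
  })
  names(rmsip_tabs) <- paste0("modes_", config$rmsip_modes)
  cosine <- do.call(rbind, lapply(results, `[[`, "cosine"))
  report <- structure(list(variants = results, rmsip = rmsip_tabs,
                           cosine = cosine,
                           manifest = list(config_hash = config_hash(
                             config[setdiff(names(config), "output_dir")]),
                             r_version = as.character(getRversion()),
                             n_variants = length(vs))),
                      class = "vd_report")
  write_report(report, config)
  report
}

write_report <- function(report, config) {
  out <- config$output_dir
  p <- function(...) file.path(out, ...)
  for (nm in names(report$variants)) {
    v <- report$variants[[nm]]
    utils::write.csv(data.frame(time_ns = v$rmsd$times,
                                rmsd_A = v$rmsd$values,
                                rg_A = v$rg$values,
                                sasa_A2 = v$sasa$values),
                     p(sprintf("%s_series.csv", nm)), row.names = FALSE)
    utils::write.csv(data.frame(resid = as.integer(names(v$rmsf)),
                                rmsf_A = unname(v$rmsf),
                                bfactor_A2 = unname(v$bfactor)),
                     p(sprintf("%s_rmsf.csv", nm)), row.names = FALSE)
    utils::write.csv(v$dccm$c, p(sprintf("%s_dccm.csv", nm)))
    if (!is.null(v$ss)) {
      utils::write.csv(v$ss$per_residue, p(sprintf("%s_ss.csv", nm)),
                       row.names = FALSE)
    }
    if (!is.null(v$distances)) {
      utils::write.csv(v$distances, p(sprintf("%s_distances.csv", nm)),
                       row.names = FALSE)
    }
    if (!is.null(v$contacts)) {
      utils::write.csv(v$contacts, p(sprintf("%s_contacts.csv", nm)),
                       row.names = FALSE)
    }
    utils::write.csv(fel_3d_export(v$fel), p(sprintf("%s_fel.csv", nm)),
                     row.names = FALSE)
  }
  summary <- list(
    manifest = report$manifest,
    rmsip = lapply(report$rmsip, function(m) as.data.frame(m)),
    cosine = report$cosine,
    pca_trace_A2 = vapply(report$variants, function(v) v$pca$trace,
                          numeric(1)),
    representative_time_ns = vapply(report$variants, function(v)
      v$representative$time_ns, numeric(1)))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Variant-minus-baseline deltas of scalar summaries
#'
#' Differences of each variant's scalar descriptors against the baseline
#' (first) variant: mean RMSD, mean Rg, mean SASA, mean RMSF, PCA trace and
#' the representative-conformer timestamp. No significance testing is applied.
#'
#' @param report a \code{vd_report}
#' @param baseline baseline variant name (default: first)
#' @return data.frame with columns \code{variant}, \code{metric},
#'   \code{value}, \code{baseline_value}, \code{delta}
#' @export
compare_variants <- function(report, baseline = names(report$variants)[1]) {
  metrics <- function(v) c(mean_rmsd_A = v$rmsd$mean,
                           mean_rg_A = v$rg$mean,
                           mean_sasa_A2 = v$sasa$mean,
                           mean_rmsf_A = mean(v$rmsf),
                           pca_trace_A2 = v$pca$trace)
  base <- metrics(report$variants[[baseline]])
  rows <- lapply(names(report$variants), function(nm) {
    m <- metrics(report$variants[[nm]])
    data.frame(variant = nm, metric = names(m), value = unname(m),
               baseline_value = unname(base), delta = unname(m - base))
  })
  do.call(rbind, rows)
}
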