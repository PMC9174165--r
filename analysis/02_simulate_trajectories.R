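#!/usr/bin/env Rscript
# Stage 2: synthetic replica trajectories for the wild-type and the three
# high-risk variants.
#
# Real 1.5 microsecond MD ensembles for these systems are not deposited, so
# the study conditions are emulated at desk scale: a 24-residue backbone
# peptide whose interior forms an alpha-helical segment (standing in for the
# CDR2 helix), three replicas per system, and per-variant fluctuation
# amplitudes chosen so the variants are visibly more mobile than the
# wild-type -- the qualitative regime the variant comparison probes. Each
# replica carries a short initial drift so the equilibration-trimming stage
# has something to cut.

library(vardyn)

out <- file.path("results", "trajectories")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_res <- 24L
pattern <- paste0("CC", strrep("H", 10), strrep("C", 12))
pep <- build_ideal_peptide(n_res, pattern, first_resid = 40L)
ref <- frame_coords(pep)

# per-system isotropic fluctuation variance (A^2 per coordinate); variants
# are progressively less rigid, emulating their destabilised loops
systems <- list(WT = 0.015, W50S = 0.035, R52C = 0.030, D104G = 0.040)
n_frames <- 150L   # 15 ns per replica at dt = 0.1 ns
n_replicas <- 3L
base_seed <- 20220601L

manifest <- data.frame()
for (vn in names(systems)) {
  for (r in seq_len(n_replicas)) {
    seed <- base_seed + 100L * match(vn, names(systems)) + r
    drift <- with_seed(seed, matrix(rnorm(3 * n_atoms(pep), sd = 0.002),
                                    n_atoms(pep), 3))
    eq <- gen_drift_ensemble(ref, drift, sqrt(systems[[vn]]), 40L,
                             seed = seed, topology = pep$topology)
    ref_eq <- frame_coords(eq, 40L)
    prod <- gen_gaussian_ensemble(ref_eq, systems[[vn]], n_frames,
                                  seed = seed + 7L,
                                  topology = pep$topology)
    traj <- concat_trajectories(list(eq, prod))
    path <- file.path(out, sprintf("%s_rep%d.pdb", vn, r))
    write_multi_model_pdb(traj, path)
    manifest <- rbind(manifest,
                      data.frame(variant = vn, replica = r, path = path,
                                 n_frames = n_frames(traj), seed = seed))
  }
}
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
cat(sprintf("Wrote %d replicas (%d systems x %d): %d+%d frames each.\n",
            nrow(manifest), length(systems), n_replicas, 40L, n_frames))
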