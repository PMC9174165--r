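# vardyn — variant-impact analysis of protein MD ensembles

`vardyn` is an R package plus analysis workflow for asking how deleterious
missense variants reshape a protein's conformational dynamics. It was built
around the TREM2 immunoglobulin domain, whose three apical
complementarity-determining loops (CDR1 = residues 40–47, CDR2 = 67–78,
CDR3 = 115–120; anchors His43/Leu72/Ser116) mediate ligand recognition and
are remodelled by disease-linked variants such as W50S, R52C and D104G.

The package covers the full chain from variant prioritisation to ensemble
analysis:

* **Consensus variant scoring** — per-SNP vote counts over K binary
  predictor calls, a ≥ 15-of-17 high-risk rule, and a pairwise
  tool-agreement matrix using the phi coefficient (Pearson correlation of
  binary calls).
* **Trajectory descriptors** — Kabsch superposition; RMSD to the initial
  structure; radius of gyration; Shrake–Rupley SASA (1.4 Å probe, 960
  deterministic sphere points); RMSF about the iterated mean structure; and
  B = (8π²/3)·RMSF².
* **Correlated motion** — the dynamic cross-correlation matrix
  C_ij = ⟨Δr_i·Δr_j⟩ / (⟨Δr_i²⟩⟨Δr_j²⟩)^{1/2} on Cα displacements.
* **Essential dynamics** — PCA of the positional covariance (eigenvalues in
  Å², trace = total variance), RMSIP subspace overlap over the first 3/10
  modes, cosine-content convergence diagnostics (< 0.1 ⇒ convergent), and
  porcupine/mode-fluctuation exports.
* **Secondary structure** — Kabsch–Sander hydrogen-bond energies
  (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN), bond < −0.5 kcal/mol)
  with α/3₁₀/strand occupancy fractions per residue and per region.
* **Loop geometry** — anchor Cα–Cα distance series and inter-region contact
  occupancy (heavy-atom cutoff 4.5 Å) with the strict > 10 % persistence
  filter.
* **Free-energy landscapes** — Boltzmann inversion
  G_i = −k_B·T·ln(N_i/N_max) at 300 K over the (RMSD, Rg) plane, plus
  lowest-energy representative-conformer extraction.
* **Synthetic ensembles** — seeded generators (Gaussian with planted
  covariance, equilibration drift, two-basin switching, ideal-geometry
  peptides, predictor call tables) so every stage is testable with known
  ground truth and no MD engine.

Trajectories are multi-model PDB files (one MODEL per frame); all
coordinates are in Å, times in ns.

## Worked example

The numbered scripts under `analysis/` run the study workflow end to end
and write their tables under `results/`:

```sh
Rscript analysis/01_consensus_voting.R
Rscript analysis/02_simulate_trajectories.R
Rscript analysis/03_full_pipeline.R
Rscript analysis/04_landscape_recovery.R
```

Stage 1 applies the consensus rule to the packaged 228 × 17 call table (a
synthetic reconstruction of the unpublished predictor matrix; see the
vignette) and prints:

```
Scored 228 SNPs across 17 tools.
High-risk SNPs (>= 15 votes): rs549402254, rs749358844, rs1409131974
Most permissive tool: DANN (79 calls); most conservative: MetaLR and FATHMM.
Tools correlating negatively with the consensus: FATHMM, VEST3
```

i.e. exactly the three known high-risk TREM2 variants survive the
≥ 15-of-17 filter. Stage 3 runs the full pipeline on simulated wild-type and
variant replicas — trimming each replica to its equilibrated tail,
concatenating, and computing all descriptors; the variants are planted with
larger fluctuation amplitudes and duly show larger PCA traces and positive
RMSF deltas against the wild-type:

```
PCA traces (A^2):
   WT  W50S  R52C D104G
2.214 3.944 3.303 4.658
Cosine contents (convergent when < 0.1): 36 of 36 convergent
```

Stage 4 calibrates the free-energy landscape on a planted 70/30 two-basin
ensemble, whose basin gap should be ln(0.7/0.3) ≈ 0.847 kT:

```
Occupied bins: 2 of 400; basin gap 0.832 kT (theory 0.847 kT).
Representative conformer: frame 2331 at 233.0 ns (state A).
```

In R, the same machinery is available directly:

```r
library(vardyn)
tab <- read_call_table(system.file("extdata", "trem2_calls_synthetic.csv",
                                   package = "vardyn"))
filter_high_risk(tab, threshold = 15)
#> [1] "rs549402254"  "rs749358844"  "rs1409131974"

pep <- build_ideal_peptide(12, "H")        # ideal alpha-helix
table(assign_ss(frame_coords(pep), pep$topology))
#>  C  H
#>  2 10
```

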