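---
title: "Variant-impact trajectory analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-impact trajectory analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vardyn)
```

## The problem

TREM2 is a microglial immune receptor whose immunoglobulin (Ig) ectodomain
binds anionic ligands through three apical complementarity-determining loops
(CDR1 = residues 40–47, CDR2 = 67–78, CDR3 = 115–120 in 5UD7 numbering, with
His43, Leu72 and Ser116 as conventional anchor residues). Missense variants
in the Ig domain are linked to neurodegenerative disease, plausibly by
remodelling loop dynamics and the positively charged putative
ligand-interacting region. `vardyn` implements the complete analysis chain
used to characterise such variants: consensus scoring of variant-effect
predictions, and ensemble analysis of molecular-dynamics (MD) trajectories
of wild-type and mutant structures.

Two design constraints shape the package. First, every analysis stage is
exercised end-to-end on *synthetic* ensembles with known ground truth,
because the original microsecond-scale trajectories are not deposited and
cannot be regenerated at desk scale. Second, residue numbering is taken
verbatim from the input PDB so that literature region definitions apply
without re-indexing.

## Consensus variant scoring

Seventeen heterogeneous predictors (SIFT, PolyPhen, CADD, DANN, FATHMM, …)
are reduced to binary deleterious/neutral calls per SNP. The per-SNP vote
count is the number of tools calling the variant deleterious, with missing
calls excluded rather than imputed; variants reaching a configurable
threshold (default 15 of 17) are flagged high-risk. Inter-tool agreement is
summarised by the phi coefficient — Pearson correlation of the binary call
vectors — computed over SNPs where both tools made a call. Phi was chosen
because binary calls are the only common denominator across tools with
incompatible score scales; when raw scores are available a score-based
Pearson matrix can be requested instead, and constant call columns yield
`NA` rather than a fabricated zero.

The shipped table `inst/extdata/trem2_calls_synthetic.csv` is a *synthetic
reconstruction*: the published facts it reproduces are the 228-SNP × 17-tool
shape, exactly three high-risk SNPs (rs549402254, rs749358844, rs1409131974)
at ≥ 15 votes, DANN as the most permissive tool, FATHMM/MetaLR as the most
conservative, and negative average correlation of FATHMM and VEST3 with the
remaining tools. Individual calls for the other 225 SNPs carry no biological
meaning.

## Trajectory descriptors

All deviation statistics rest on Kabsch least-squares superposition (SVD
with reflection correction, so `det(R) = +1`). Conventions:

* **RMSD** is computed per frame against the *first frame* of each replica —
  the convention for equilibration monitoring — over the backbone
  {N, CA, C, O} selection by default.
* **RMSF** uses the *iteratively converged mean structure* as reference
  (superpose → re-average, tolerance 1e-7 Å, ≤ 50 iterations), reported at
  Cα. Note that rigid-body fitting absorbs six degrees of freedom, deflating
  isotropic RMSF by roughly `sqrt(1 - 2/N)`; with `superpose = FALSE` the
  estimator is exact for frames already in a common frame.
* **Radius of gyration** uses unit weights by default, atomic masses on
  request.
* **SASA** is Shrake–Rupley with a 1.4 Å probe, fixed per-element radii
  (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å) and 960 deterministic
  Fibonacci-lattice sphere points (minimum 32; empirical accuracy ≈ 0.5 %
  against a 10⁵-point evaluation). Points lying exactly on coincident
  expanded surfaces are split evenly so degenerate geometries remain
  well-defined. Output is Å², with nm² scaling available.
* **B-factors** are `B = (8π²/3)·RMSF²`, the putty-representation scale.
* Per-frame series are summarised by mean, quartiles and a Gaussian-kernel
  density (Silverman bandwidth, 512-point grid).

## Correlated motion and essential dynamics

The dynamic cross-correlation matrix uses the normalised displacement
covariance

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\left(\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle\right)^{1/2}},$$

computed on Cα atoms after superposition onto the converged mean structure
(removing rigid-body motion that would inflate correlations). Zero-variance
atoms yield `NA` rows. PCA diagonalises the positional covariance of the
same superposed coordinates; the *sample* covariance (divisor `T − 1`) is
used, matching common practice, and eigenvector signs are fixed by making
each vector's largest-magnitude component positive so porcupine orientations
are reproducible. The trace (sum of eigenvalues, Å²) is the ensemble's total
positional variance.

Subspace similarity uses RMSIP over the first 10 modes (3 also reported):

$$\mathrm{RMSIP} = \sqrt{\tfrac{1}{n}\sum_{i\le n}\sum_{j\le n}
(v_i^a \cdot v_j^b)^2}.$$

Sampling convergence uses the cosine content of each replica's first three
principal components, in the discrete form
$c_i = (2/T)\,\big(\sum_t \cos(i\pi t/T)\, p_i(t)\big)^2 / \sum_t p_i(t)^2$
with `t = 0…T−1`; values below 0.1 are labelled convergent, and the pipeline
warns (rather than fails) above that, since the quantity is a diagnostic.

## Secondary structure

Assignment follows the Kabsch–Sander model: the backbone hydrogen-bond
energy

$$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})
\ \text{kcal/mol}$$

declares a bond below −0.5 kcal/mol; two consecutive i→i+4 turns give
α-helix (H), i→i+3 gives 3₁₀ (G), bridge patterns give strand (E), isolated
turns T, with conflict priority H > E > G > T. Amide hydrogens are
reconstructed (1.0 Å from N, opposite the C(i−1)–N–CA bisector) so
heavy-atom trajectories are supported; distances under 0.5 Å are capped as
clashes; chain breaks (C–N > 2.5 Å) split assignment regions. π-helix and
bend states are folded into "other" for occupancy reporting, which returns
per-residue and per-region fractions of frames in H, G, E and other.

## Loop geometry and contacts

Inter-loop separation uses per-frame Cα–Cα distances between anchor
residues. Residue pairs across two regions are "in contact" in a frame when
their minimum heavy-atom distance is ≤ 4.5 Å — a conventional persistent-
contact cutoff, exposed as a config knob since the original criterion is not
specified — and occupancy is the exact fraction of frames `k/T`. The
persistence filter is *strict*: a pair at exactly 10 % occupancy is removed,
matching the "exceeded 10 %" rule.

## Free-energy landscapes

Over the (RMSD, Rg) plane — the documented default; any pair of per-frame
series, e.g. PC1/PC2, can be substituted — frames are histogrammed on a
100 × 100 grid (data-driven ranges, 1 % padding) and Boltzmann-inverted:

$$G_i = -k_B T \ln(N_i / N_{max}), \qquad T = 300\,\mathrm{K}.$$

The most occupied bin sits exactly at `G = 0`; empty bins are `+Inf`
(masked), never a finite cap, so minima are unambiguous. Energies are in kT
by default (kcal/mol on request; k_B·T at 300 K = 0.596 kcal/mol). A
degenerate (zero-variance) axis is an error rather than a silently collapsed
histogram; as a consequence an all-identical trajectory is rejected instead
of producing a single-bin landscape. The representative conformer is the
frame nearest the modal bin's centre in normalised bin units, with earliest-
time tie-break for determinism.

## The synthetic-data generators

The generators provide the study conditions for testing:

* `gen_gaussian_ensemble()` — stationary fluctuation with an arbitrary
  planted 3N × 3N covariance: ground truth for DCCM entries, PCA
  eigenvectors/trace and RMSF closed forms (isotropic σ gives
  RMSF = √3·σ).
* `gen_drift_ensemble()` — linear drift plus noise, emulating
  pre-equilibration relaxation; its PC-1 projection has cosine content
  near 1.
* `gen_two_state_ensemble()` — seeded Bernoulli switching between two
  reference conformations with isotropic jitter; a p = 0.7 ensemble plants a
  free-energy gap of ln(7/3) ≈ 0.847 kT.
* `build_ideal_peptide()` — poly-alanine backbones from ideal internal
  coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å) and canonical
  torsions: H (−57°, −47°), G (−49°, −26°), E (−119°, 113°), C extended
  irregular. Strand pairing places a duplicate chain by the sheet's local
  two-fold symmetry and a deterministic grid search that drives inter-chain
  amide-H···O distances to 1.95 Å without clashes.
* `gen_call_table()` — Bernoulli predictor calls with known vote counts.

All generators are bit-reproducible for a fixed seed (one private RNG stream
per call). What they deliberately do **not** emulate: force-field energetics,
solvent, anharmonic multi-basin landscapes beyond two states, side chains,
and correlated noise along the time axis (frames are exchangeable). Passing
tests therefore demonstrate the *estimators* are correct on data whose
ground truth is known — not that any MD sampling is sufficient; conclusions
about real trajectories still require the cosine-content and RMSD-plateau
diagnostics the pipeline reports.

## Pipeline defaults

`run_full_analysis()` trims each replica to its final 60 % (generalising
"keep the last 300 ns of a 500 ns run"; a config constant rather than an
automatic plateau detector, which would invent criteria the analysis never
stated), concatenates replicas onto one strictly increasing time axis with
provenance retained, and runs every stage. Key defaults: frame spacing
0.1 ns; consensus threshold 15; contact cutoff 4.5 Å; contact persistence
0.10 (strict); FEL 100 × 100 bins at 300 K; RMSIP over 3 and 10 modes;
cosine-content warning limit 0.1. The manifest records a hash of the
configuration so deterministic stages can be re-run bit-identically.

## Problem sizes

The test suite and the acceptance script exercise the estimators at sizes
chosen to make sampling error negligible relative to the asserted
tolerances while remaining desk-scale: DCCM block recovery at 10 000 frames
(±0.05), planted-eigenvector recovery at 50 000 frames (alignment > 0.99),
isotropic RMSF at 20 000 frames × 100 atoms (±2 %, which also covers the
`sqrt(1 - 2/N)` fit deflation), two-basin free-energy recovery at 10 000
frames × 10 seeds (three binomial standard errors), and the full pipeline on
12 synthetic replicas of a 24-residue peptide. The published PCA traces
(46.5–70.5 Å²) and conformer timestamps depend on the original undeposited
trajectories and are treated as descriptive, not as reproduction targets.

## Known limitations

* The PDB reader accepts only single-character altloc 'A'/' ' records and
  rejects insertion codes, by design.
* The secondary-structure module reports strand (E) from bridge patterns but
  does not label ladders or sheet topology.
* SASA has no analytic derivatives and is point-sampling limited (~0.5 % at
  960 points).
* Contact definitions are distance-based only; hydrogen-bond or salt-bridge
  typing is out of scope.
* No periodic-box handling: frames must contain whole, pre-imaged molecules.
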