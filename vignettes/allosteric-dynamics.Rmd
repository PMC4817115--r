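---
title: "Methods: trajectory analysis of allosteric modulation in a dimeric chaperone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of allosteric modulation in a dimeric chaperone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

## Scope and model

`allodyn` implements the analysis layer used to study how small allosteric
ligands modulate the conformational dynamics of a homodimeric chaperone such
as Hsp90: each protomer carries an N-terminal domain (NTD, the ATP site), a
Middle domain (MD) and a C-terminal dimerisation domain (CTD), and the
functional cycle runs through open and NTD-dimerised closed states. The
package takes molecular-dynamics trajectories (or synthetic stand-ins with
known ground truth) and computes four families of results:

1. **Distance-fluctuation (coordination propensity, CP) matrices.** For a
   residue pair $(i, j)$ with instantaneous C$\alpha$ separation $d_{ij}(t)$,
   $$\mathrm{CP}_{ij} = \left\langle \left(d_{ij} - \langle d_{ij}\rangle\right)^2 \right\rangle,$$
   the time variance of the pair distance in nm². Pairs inside one
   quasi-rigid unit have small CP; pairs spanning flexibly coupled units
   have large CP. Because CP is a function of internal distances only, it is
   exactly invariant under per-frame rigid motions and requires no
   superposition onto a reference — the implementation never aligns frames,
   and a property test asserts invariance to randomly re-oriented frames at
   1e-12 nm². Replicate matrices are combined by the element-wise mean, and
   ligand effects are read from difference matrices
   $\Delta\mathrm{CP} = \mathrm{CP}^{\mathrm{ref}} - \mathrm{CP}^{\mathrm{complex}}$
   (positive: more flexible in the reference; negative: more flexible in the
   complex).

2. **Inter-protomer geometry.** The NTD–NTD centre-of-mass distance
   distribution (backbone atoms, unweighted centroid), inter-protomer
   residue contact counts (a contact exists when any atom pair of two
   residues from different chains is strictly closer than 0.6 nm), and
   protomer axis angles: after superposing each protomer's CTD onto the
   reference structure's CTD, the angle between the principal axis of the
   N+M region and the same axis in the reference is measured per frame, and
   the per-frame difference between protomers (B − A) quantifies
   ligand-induced asymmetry.

3. **Daura (GROMOS) leader clustering** of sampled frames on a pairwise
   backbone-RMSD matrix (CTD backbone by convention): repeatedly extract the
   frame with the most neighbours within 0.2 nm together with those
   neighbours. Representatives of the top clusters (at most 10, or fewer if
   95% cumulative coverage is reached earlier) feed ensemble docking.

4. **The SDAR correlation model.** Ligand efficiency is the best-pose
   docking score divided by the ligand's heavy-atom count,
   $\mathrm{LE} = S/N_{\mathrm{heavy}}$ (kcal/mol per atom). Per compound,
   LE is averaged over a receptor ensemble — either structures from the
   ligand-free ATP-state dynamics (the docking-over-multiple-receptor-
   structures mode), representatives of each complex's own clusters, or
   plain snapshots — and the per-compound mean LE is correlated (Pearson)
   with measured activity (ATPase turnover, min⁻¹). Modes are ranked by
   |r|; the multi-receptor ATP-state mode is the most predictive on the
   published six-compound benzofuran series.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| equilibration discard | 0.25 | fraction | first quarter of each run treated as equilibration (25 of 100 ns in the original protocol) |
| contact cutoff | 0.6 | nm | conventional 6 Å any-atom residue contact |
| cluster RMSD cutoff | 0.2 | nm | standard leader-clustering neighbour radius for backbone RMSD |
| sampling stride | 0.5 | ns | frame spacing for the axis/clustering analyses, taken from the second half of the run |
| histogram bin width | 0.05 | nm | resolves the ~0.5 nm peak shifts of interest without empty bins |
| representatives | ≤10, ≥95% coverage | — | ensemble-docking budget vs coverage of sampled variability |

Coordinates are held in nm throughout (PDB I/O converts from/to Å at the
boundary), so the cutoffs above apply without unit juggling. Residue
numbering is taken verbatim from the input files; protomers are identified
by chain, with chain A the first chain unless overridden.

## Numerical choices

* **CP convention.** "Distance fluctuation" is implemented as the
  *variance* (nm²) of the pair distance, with the population (divide-by-N)
  convention; the choice is recorded in the matrix metadata. The standard
  deviation would carry the same structure on a different scale.
* **Streaming accumulation.** CP uses a single-pass Welford update over
  frames, so memory is bounded by two $N_{res}^2$ accumulators regardless
  of trajectory length. Tiny negative variances from cancellation are
  clamped to zero and the matrix is symmetrised exactly.
* **Superposition.** Kabsch/SVD with a determinant correction so the
  rotation is always proper; fewer than three fit atoms or a collinear fit
  set raise a degenerate-fit error rather than returning an arbitrary
  rotation.
* **Axis sign and degeneracy.** "Inertia axes" are realised as the
  largest-eigenvalue eigenvector of the unweighted gyration tensor — the
  long axis, appropriate because protomers and their N+M regions are
  strongly prolate (the smallest-moment axis of the inertia tensor points
  the same way for such shapes). The ±v ambiguity is resolved by a dot
  product against the reference axis, so angle series never jump to
  supplements; a near-degenerate top eigenvalue pair raises an error that
  reports the gap.
* **Clustering tie-break.** When two frames tie on neighbour count the
  lower frame label wins, which makes the partition deterministic and
  (keyed on original labels) invariant to presentation order. The neighbour
  test is strictly `< cutoff`, consistent with the contact convention.
* **Pearson on printed values.** The shipped benzofuran table carries the
  published per-compound mean LEs at two decimals. Correlating those
  printed values against ATPase rates reproduces the published correlation
  row to within one unit of its last printed digit (−0.90 and −0.57
  exactly; −0.693 vs the printed −0.70 for the clusters column, the
  residual being the rounding of the LE inputs). The permutation p-value
  offered by `pearson_r()`/`sdar_correlate()` is an extra of this package,
  not part of the original model.

## What the synthetic generator emulates — and what it does not

`generate_dimer_trajectory()` builds a two-chain dimer of rigid domain
blocks (NTD, MD, CTD stacked along the protomer axis; four-atom N/CA/C/O
"residues" so backbone and C$\alpha$ selections work unmodified) and lets
tests impose, with exact ground truth:

* per-atom isotropic jitter (default 0.02 nm, the positional spread of a
  backbone atom in a folded protein);
* a chosen centre–centre distance fluctuation for named domain pairs
  (applied along the fixed pair axis, so the distance variance equals
  σ² exactly; per-atom jitter adds 2σ²_pos to C$\alpha$-pair variances);
* a linearly growing distortion of protomer B's N+M blocks, implemented as
  a hinge rotation about an axis orthogonal to the N+M principal axis so
  the axis-angle readout equals the schedule exactly in the noiseless
  limit (a rotation about the long axis itself would be invisible to a
  principal-axis analysis);
* an NTD–NTD separation step at the trajectory midpoint (two condition
  ensembles in one run), so the distance-histogram peaks of the two halves
  are separated by exactly the imposed amount.

`generate_score_table()` constructs activities, heavy-atom counts and
per-receptor docking scores such that the Pearson correlation between true
mean LE and activity equals the target exactly before receptor-level noise
is added. Calling it with the same seed and different targets yields the
same activities and ligands, which is how multi-mode ranking experiments
share a common activity table.

Neither generator is physical: there are no bonds, no energetics, no
solvent, and domain blocks are internally rigid apart from isotropic
jitter. Passing tests therefore demonstrate that the *estimators* recover
imposed statistical structure — not that real Hsp90 trajectories would show
these signals. The published MD observables on real trajectories are out of
reach at desk scale (the underlying trajectories were not deposited), which
is exactly why the synthetic route carries the validation load.

## Problem sizes used in the shipped checks

The validation suite runs, as the package's own choice of problem sizes:
CP recovery on 5000 frames of a 48-atom dimer (sampling error of a
distance variance at 5000 frames is ~2%, comfortably inside the 15%
acceptance band); axis-angle recovery on 50 noiseless and 100 noisy frames
with 24 atoms per domain (six residues per domain gives the CTD anchor
enough atoms that the fit error stays well under the 2° band at 0.02 nm
noise); clustering oracle comparisons on 60-frame matrices plus a
100-frame 12-cluster fixture; and 200 seeded repetitions of the
three-mode SDAR ranking experiment at score noise 0.1.

## Known limitations

* Trajectory input is multi-model PDB, GRO (single frame) and DCD; XTC/TRR
  must be converted externally. Trajectories are assumed whole-molecule
  (no periodic-boundary reconstruction).
* Quasi-rigid domains are read off the CP matrix visually or via the
  chain-block summary (`glance()`); no automatic segmentation is provided.
* The package consumes docking-score tables; it performs no docking,
  re-scoring or pose generation. The single-best-pose control mode exists
  (a one-column score table) but has no published anchor to compare
  against.
* FRET closure-rate correlations run through the same arithmetic as ATPase
  correlations when a `closure_rate` column is supplied; no closure values
  ship with the package because none were published at full precision.
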