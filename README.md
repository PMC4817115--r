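# allodyn

Trajectory analysis of allosteric modulation in dimeric proteins, built
around the Hsp90 chaperone problem: small ligands binding ~65 Å from the
ATP site can *activate* the chaperone's ATPase by reshaping its
conformational dynamics, and the question is which computable observables
track that activation.

`allodyn` is for computational structural biologists who have (or simulate)
MD trajectories of a two-protomer dimer and docking scores for a compound
series, and want the standard read-outs connecting dynamics to activity:

* **Coordination propensity (CP)**: per residue pair (i, j), the time
  variance of the Cα–Cα distance, CP_ij = ⟨(d_ij − ⟨d_ij⟩)²⟩ (nm²), with
  replica averaging and reference-minus-complex difference maps. Low CP
  marks quasi-rigid units, high CP flexible coupling; the statistic is
  alignment-free and exactly invariant under rigid motions of each frame.
* **Inter-protomer geometry**: NTD–NTD centre-of-mass distance
  distributions (backbone atoms), any-atom residue contact counts at a
  strict 0.6 nm cutoff, and CTD-anchored protomer axis angles — after
  superposing each protomer's CTD on a reference, the angle of the N+M
  principal axis against the reference axis, and the B − A difference as
  the asymmetry readout.
* **Daura/GROMOS leader clustering** on a pairwise CTD-backbone RMSD
  matrix (0.2 nm neighbour cutoff), with representative selection capped
  at ten structures or 95% cumulative coverage for ensemble docking.
* **The SDAR model** (structure–dynamics–activity relationship): ligand
  efficiency LE = score / heavy-atom count, averaged per compound over a
  receptor ensemble, then Pearson-correlated with measured ATPase turnover
  (min⁻¹); ensemble modes are ranked by |r|.

A synthetic-data module generates dimer trajectories and docking-score
tables with exact ground truth (imposed inter-domain distance variances,
protomer distortions, separation shifts, target LE–activity correlations),
so every estimator is validated against construction without any external
data.

## Worked example

```r
library(allodyn)

# published six-compound benzofuran series: mean LE per ensemble mode vs ATPase
tab <- benzofuran_activity_table()
correlate_le(tab, tab[, c("compound_id", "atpase_rate")])
#> # A tibble: 3 × 5
#>   mode              activity         r     n p_perm
#>   <chr>             <chr>        <dbl> <int>  <dbl>
#> 1 dmrs_atp_only     atpase_rate -0.905     6     NA
#> 2 complex_clusters  atpase_rate -0.693     6     NA
#> 3 complex_snapshots atpase_rate -0.567     6     NA
```

Averaging LE over the ten ATP-state receptor structures (`dmrs_atp_only`)
correlates with ATPase stimulation at r ≈ −0.90 — more negative LE, faster
ATP turnover — and beats averaging over the complexes' own cluster
representatives (−0.69) or snapshots (−0.57).

```r
# synthetic dimer with a 30° distortion imposed on protomer B
sim <- generate_dimer_trajectory(
  dimer_sim_spec(n_frames = 200, protomer_b_twist = 30, seed = 1)
)
sim$ensemble
#> <trajectory_ensemble> 48 atoms, 200 frames, chains: A, B (replica rep1)

dm <- sim$truth$domain_map
mk <- function(ch, doms, filt) residue_selection(
  dm[dm$chain_id == ch & dm$domain %in% doms, c("chain_id", "residue_id")],
  atom_filter = filt
)
angles <- protomer_angles(
  sim$ensemble, sim$reference,
  ctd_selections = list(A = mk("A", "CTD", "backbone"), B = mk("B", "CTD", "backbone")),
  nm_selections  = list(A = mk("A", c("NTD", "MD"), "c_alpha"), B = mk("B", c("NTD", "MD"), "c_alpha"))
)
tail(angle_asymmetry(angles), 3)
#> # A tibble: 3 × 3
#>   frame  time b_minus_a
#>   <dbl> <dbl>     <dbl>
#> 1   198  19.7      27.5
#> 2   199  19.8      29.1
#> 3   200  19.9      29.0
```

The B − A asymmetry series climbs to ≈30° at the final frame: the imposed
protomer-B distortion is recovered through the CTD-anchored axis analysis
(the residual ~1° is the imposed 0.02 nm positional noise).

```r
sel <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
cp <- compute_cp(sim$ensemble, sel)   # discards the first 25% as equilibration
glance(cp)
#> # A tibble: 4 × 4
#>   chain_i chain_j mean_value n_pairs
#>   <chr>   <chr>        <dbl>   <int>
#> 1 A       A         0.000789      30
#> 2 A       B         0.00457       36
#> 3 B       A         0.00457       36
#> 4 B       B         0.00109       30
```

Within-protomer pairs fluctuate far less than cross-protomer pairs (the
twisting protomer B also fluctuates more than A) — the quasi-rigid-domain
signature the CP analysis is designed to expose. `tidy()` returns the full
long-form matrix and `autoplot()` draws the blue–white–black difference
map; `run_pipeline(run_config(...))` chains all stages and writes CSVs
plus a checksummed manifest.

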