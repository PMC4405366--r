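# idpens

Conformational-ensemble analysis for intrinsically disordered proteins
(IDPs), built around the 61-residue transactivation domain (TAD) of the
tumor suppressor p53 — a disordered region that carries three transient
helices (residues 18–27, 40–44 and 48–52) and whose cancer-associated point
mutations (E17D, K24N, N29K/N30D, D49Y, W53G) subtly reshape its ensemble.

Simulated ensembles of IDPs are characterized by statistics over thousands
of conformations, and judged by back-calculated NMR observables.  `idpens`
implements that tool chain:

- **Ensemble I/O** — multi-model PDB read/write (one `MODEL` per
  conformation), atom/frame selection, frame weights.
- **Local structure** — helix assignment from backbone φ/ψ dihedrals or
  Cα virtual torsions (minimum run of 3 residues), per-residue helicity
  profiles with independent-run uncertainties, helical-substate
  (segment start × end) histograms.
- **Tertiary structure** — residue–residue contact probability maps
  (minimal heavy-atom distance ≤ 4.2 Å, boundary inclusive, or Cα
  distance ≤ 8 Å), map correlation/RMSD convergence metrics, inter-residue
  distance distributions, radius of gyration.
- **PRE back-calculation** — paramagnetic relaxation enhancement
  intensity ratios for site-directed spin labels (D7C, E28C, A39C, D61C):

  I_ox/I_red = R₂ · exp(−R₂ₛₚ·t) / (R₂ + R₂ₛₚ),
  R₂ₛₚ = (K/r⁶) · (4τ_c + 3τ_c/(1 + ω_H²τ_c²))

  with K = 1.23×10⁻³² cm⁶ s⁻², τ_c = 3.3 ns, ω_H = 2π·600 MHz,
  R₂ = 16 s⁻¹, t = 9.8 ms, and r the ensemble-averaged (⟨r⁻⁶⟩^(−1/6) or
  ⟨r⟩) Cα–Cα distance between label site and target residue.
- **Clustering** — fixed-radius conformational clustering at 5 Å
  superposed Cα RMSD (leader pass + minimax-centroid refinement), with
  size-band population summaries.
- **Comparison & convergence** — wild-type vs. mutant helicity deltas with
  window flagging, convergence reports between independent runs, RDC
  uniform scaling, secondary chemical shifts against a coil reference.
- **Synthetic ensembles** — a seeded helix–coil Monte Carlo generator
  producing Cα-trace (or N-CA-C backbone) ensembles with *known*
  per-residue helicity, excluded volume and biased transient long-range
  contacts, so every stage above is testable against ground truth.

## Worked example

```r
library(idpens)

## two independent "runs" of a wild-type-like synthetic ensemble:
## 10% helicity on 18-27, 6% on 40-44 and 48-52, 4000 frames each
run1 <- generate_ensemble(wt_like_spec(n_frames = 4000, seed = 1))
run2 <- generate_ensemble(wt_like_spec(n_frames = 4000, seed = 2))

prof <- pool_profiles(
  helicity_profile(assign_helix(run1$ensemble)),
  helicity_profile(assign_helix(run2$ensemble)))
region_mean_helicity(prof, 18, 27)
#> [1] 0.102025

convergence_report(run1$ensemble, run2$ensemble)
#> Convergence report (run 1 vs run 2):
#>   helicity profile RMSD: 0.0024
#>   contact map correlation: 0.997, RMSD: 0.0034

## K24N-like variant: the 18-27 helix drops from ~10% to ~5%
mut <- generate_ensemble(k24n_like_spec(n_frames = 4000, seed = 3))
mut2 <- generate_ensemble(k24n_like_spec(n_frames = 4000, seed = 4))
mprof <- pool_profiles(helicity_profile(assign_helix(mut$ensemble)),
                       helicity_profile(assign_helix(mut2$ensemble)))
delta_helicity(prof, mprof)
#> Helicity delta report (variant - reference):
#>   residues 18-27: delta -0.052 (uncertainty 0.005)  [modulated]
#>   residues 40-44: delta +0.005 (uncertainty 0.008)
#>   residues 48-52: delta +0.001 (uncertainty 0.004)

## PRE profile for the E28C spin label
pre <- pre_profile(run1$ensemble, "E28C")
pre_ratio(15)   # intensity ratio at 15 Angstrom
#> [1] 0.4585619
```

The helicity delta report above reads: the variant ensemble lost 5.2
percentage points of helix in residues 18–27 (well beyond the
between-run uncertainty, hence `[modulated]`), while the two distal
helices are unchanged.

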