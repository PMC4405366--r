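---
title: "Methods: ensemble statistics, NMR back-calculation and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble statistics, NMR back-calculation and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`idpens` analyzes heterogeneous conformational ensembles of intrinsically
disordered proteins (IDPs): collections of frames (conformations) over one
topology, optionally weighted.  This vignette records the models and
conventions behind each analysis, the reasoning behind parameters whose
values were genuinely open, and the limits of what the synthetic-ensemble
validation can demonstrate.

## Helix assignment and helicity profiles

There is no universally agreed dihedral criterion for "helical" in
disordered ensembles, so the package fixes one explicitly and exposes it as
a backend choice:

* **phi-psi** (requires N, CA, C atoms): a residue is flagged when
  φ ∈ (−100°, −30°) and ψ ∈ (−67°, −7°) — a standard α-basin window.
* **ca-torsion** (works on Cα traces): the virtual torsion over Cα atoms
  *i..i+3* flags its two interior residues when it lies in (30°, 70°),
  the α-helical band of the Cα virtual torsion.

In both backends a flagged residue counts as helical only inside a run of
at least **3** consecutive flagged residues (just under one helical turn);
shorter runs are relabeled coil.  Chain-terminal residues whose dihedrals
are undefined are coil.  The same ≥3-run rule is used by the synthetic
generator's ground truth, so assignment and generation share one
definition of helix.

A helicity profile is the weighted column mean of the binary state matrix.
Profile uncertainty follows the independent-run convention: when a profile
is pooled from two independently started runs (`pool_profiles()`), the
per-residue uncertainty is the absolute difference between the runs — the
same convention used to judge convergence of paired folding/control
simulations.  `profile_rmsd()` (root-mean-square difference over residues)
is the scalar convergence metric.

Helical substates are maximal runs within one frame, histogrammed over
(start residue, end residue); cell values are weighted per-frame
frequencies, so the cell sum equals the mean number of helical segments
per frame and may exceed 1.

## Contact maps and distance statistics

Two residues are "in contact" when their **minimal heavy-atom distance is
≤ 4.2 Å** (boundary inclusive).  For Cα-trace ensembles, which carry no
side chains, the package uses a Cα–Cα criterion with a default cutoff of
**8 Å** — an explicit package convention, not a literature value.  Pairs
with sequence separation |i−j| < 4 are masked, so maps report long-range
structure; the mask width is a parameter.  Map convergence statistics
(Pearson correlation, entrywise RMSD) run over the unmasked upper triangle
only, to avoid double-counting the symmetric entries.

Distance distributions are weighted histograms of per-frame Cα–Cα
distances with their weighted mean and SD; the end-to-end distance is the
first-vs-last-residue special case.  The radius of gyration is
mass-uniform over the selected atoms.

## PRE back-calculation

A nitroxide spin label broadens amide resonances with an r⁻⁶ dependence.
The observable is the oxidized/reduced HSQC intensity ratio

$$\frac{I_{ox}}{I_{red}} = \frac{R_2\,e^{-R_{2sp}t}}{R_2 + R_{2sp}},
\qquad
R_{2sp} = \frac{K}{r^6}\left(4\tau_c + \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right)$$

with defaults K = 1.23×10⁻³² cm⁶s⁻² (single electron–proton pair),
τ_c = 3.3 ns, ω_H for a 600 MHz spectrometer, R₂ = 16 s⁻¹, t = 9.8 ms.
Distances enter in cm; the package converts from Å internally.

Two conventions are deliberately exposed rather than silently chosen:

* **ω_H**: parameter sets are often quoted as "ω_H = 600 MHz" without
  stating whether the spectral-density term uses angular frequency.  The
  default is **angular** (2π·600 MHz), the standard spectral-density form;
  `omega_convention = "linear"` is available.  At these defaults the
  dispersive term is ~3 orders of magnitude below the 4τ_c term, so the
  choice barely moves the ratio — the tests assert this dominance.
* **distance averaging**: "ensemble-averaged distance" can mean ⟨r⟩ or the
  PRE-relevant ⟨r⁻⁶⟩^(−1/6).  The default is **r6** (physically correct
  for PRE: broadening is dominated by close approaches); `arithmetic` is
  available.  The power-mean inequality guarantees r6 ≤ arithmetic, which
  the tests assert ensemble-wide.

Ensembles carry no explicit label atom, so Cα–Cα distances proxy the
electron–proton separation.  The label-site residue itself is reported as
ratio 0 (its amide is fully broadened) and excluded from correlations with
experimental profiles.

## Fixed-radius clustering

The clustering contract is a deterministic leader + refinement scheme on
superposed Cα RMSD (proper-rotation Kabsch):

1. Leader pass in frame order — join the nearest centroid within the
   radius, else found a new cluster.
2. Three refinement passes (configurable) — re-pick each centroid as the
   member minimizing the maximum RMSD to its cluster mates (minimax
   member), then re-assign all frames, founding new clusters only when a
   frame exceeds the radius to every centroid.

Ties break toward the lower cluster id; output clusters are sorted by
descending population.  This is documented as an approximation of the
kclust-style fixed-radius tools used in the simulation literature, not an
exact reimplementation of any of them; the guaranteed invariant is that
every member lies within the radius of its centroid frame.  The default
radius of 5 Å Cα RMSD is the conventional cutoff for a ~60-residue
disordered chain; ensembles are conventionally subsampled to their last
4000 production frames before clustering.

Clustering a fully disordered Cα-trace ensemble at 5 Å yields almost
entirely singleton clusters — random coils of a 61-mer are pairwise ~15 Å
apart — so the meaningful validation is planted-partition recovery:
well-separated reference conformers (inter-conformer RMSD ≥ 3× radius)
with small jitter (≤ 0.5× radius) must be recovered exactly, which the
tests assert.

## Mutant comparison and flagging

`delta_helicity()` reports per-residue deltas `variant − reference` with
propagated uncertainty √(u_a² + u_b²) and window summaries over the three
transient helices (18–27, 40–44, 48–52 by default).  A window is flagged
"modulated" when its |mean delta| exceeds `n_sigma` times the combined
window uncertainty.  The default `n_sigma = 1` mirrors the plain
uncertainty-comparison convention of the profile uncertainties themselves;
for screening, `n_sigma = 2` keeps the false-positive rate of
identical-ensemble comparisons at the few-percent level (asserted in the
tests).  No multiple-testing correction is applied across the three
windows — they are few and reported transparently, not selected.

RDC comparison implements only the downstream uniform scaling: the
least-squares scalar s = Σ(pred·exp)/Σ(pred²) plus the Pearson
correlation; prediction of RDCs themselves is out of scope.  Secondary
chemical shifts are `observed − coil reference(residue type)`, with the
coil table supplied by the user; negative Hα shifts are the helical
signature.

## The synthetic-ensemble generator

The generator is a statistical stand-in for simulated disordered
ensembles — not a physical simulator (no force field, no solvent, no
kinetics).  It exists so that every analysis stage can be validated
against known ground truth.

**States.** Each frame draws an independent helix/coil state vector:
residue *i* is helical with its propensity p_i, with odds multiplied by
e^{±c} according to the previous residue's state (cooperativity c;
c = 0 gives exact independent Bernoulli marginals).  Runs shorter than 3
are relabeled coil — the assignment rule, applied at the source.  The
realized per-residue helicity (column means of the state matrix) is the
exact ground truth.  `expected_helicity_exact()` computes the
post-relabeling expectation by enumerating all 2^L patterns of a segment,
and `propensity_for_helicity()` inverts it, which is how the presets hit
10% realized helicity on 18–27 (wild-type-like), 5% (K24N-like), and
halved distal helicity (N29K/N30D-like) — the magnitudes reported for
well-converged ensembles of p53-TAD and its mutants.  Frames are mutually
independent by construction, so binomial error bars are exact.

**Coordinates.** Helical residues get ideal Cα helix geometry (virtual
bond 3.8 Å, virtual angle 91° ± 3°, virtual torsion +50° ± 5°, ≈1.5 Å
rise/residue); coil residues draw virtual angles uniformly on (75°, 140°)
and virtual torsions uniformly on (−180°, 180°] **excluding** the (30°,
70°) detection window.  The exclusion is deliberate: if coil torsions
could fall in the helical band, adjacent chance hits would fabricate ≥3
runs in roughly half of all frames, and generated and measured helicity
could never agree exactly.  With the exclusion, the ca-torsion assignment
reproduces the ground-truth states *bit-exactly* (given zero propensity at
the two terminal residues, whose dihedrals are undefined) — a stronger
property than statistical agreement, and the tests assert it.  The N-CA-C
mode works identically with (φ, ψ) = (−62°, −41°) and the α-basin box
excluded from coil draws.

**Excluded volume.** No two Cα atoms separated by ≥3 residues may come
closer than the excluded-volume radius (default 4 Å).  The constraint is
enforced during growth: a clashing atom placement is redrawn locally (up
to 30 times) before the whole frame is discarded and regrown.  Local
redraws make 61-mer generation ~60× cheaper than whole-frame rejection at
identical guarantees (the returned ensemble satisfies the constraint
exactly); the cost is a mild, deliberate enrichment of conformations that
survive growth, which is part of this generator's definition of its coil
ensemble.  A frame-rejection rate above 99.9% raises an error advising a
parameter change.

**Transient long-range contacts.** Contact biases (i, j, target
probability) are applied by rejection against square-well contact
potentials: a grown frame is accepted with probability
exp(Σ s_k·c_k − Σ max(s_k, 0)), where c_k indicates the contact (Cα
distance ≤ 8 Å) and s_k the well depth.  Acceptance-rejection (rather
than a Markov chain over frames) keeps frames independent draws from the
reweighted distribution.  `calibrate_contact_strengths()` sets the depths
from the exact single-pair logit solution against an unbiased pilot, then
refines over two biased-pilot rounds — necessary because rare baselines
cannot be pinned down by one small pilot.  The wild-type-like preset
biases five pairs at sequence separations 8–12 to probabilities 0.10–0.12,
inside the 0.06–0.2 band where transient-contact maps of p53-TAD show
structure.  Separations of 20–35, where the real TAD's helix–helix
contacts live, have ~10⁻³ baseline probability in an ideal-chain model
and are reachable by exact rejection only for a single pair (the tests
demonstrate one such pair at separation 40); enriching five of them at
once is not feasible without a Markov chain, which would break frame
independence.  This is a stated limitation of the stand-in, not of the
analysis code.

**What the synthetic validation does and does not show.**  Passing tests
demonstrate that the statistics, back-calculations and clustering are
computed correctly and recover known ground truth at realistic sample
sizes (4000 frames, helicities of 3–10%, contact probabilities of
0.06–0.2).  They do not show that any force field reproduces p53-TAD:
the generator's chains are more expanded (Rg ≈ 18–19 Å) than simulated
compact ensembles, carry no side chains, no sequence-specific energetics
beyond the imposed propensities, and no correlation between helicity and
compaction.

## Numerical choices and problem sizes

* Superposition uses SVD-based Kabsch with the determinant sign
  correction (proper rotations only); degenerate inputs (< 3 atoms) are
  errors.  The test oracle is an independently written quaternion method.
* Contact cutoffs are boundary-inclusive (`<=`), matching the
  "no greater than" convention.
* Weighted profile/histogram computations renormalize weights to sum 1
  and reject negative weights.
* Ties in clustering (equidistant centroids) go to the lower cluster id,
  making results order-deterministic; `which.min` implements this
  directly.
* The test suite and the acceptance script size their ensembles at 4000
  frames (the conventional production-segment size) for recovery tests
  and 150–2000 frames for exactness and property tests — enumeration
  oracles are exact at any n, so smaller sizes lose no rigor there.
* All generation randomness derives from a single integer seed through
  R's RNG; C++ growth code draws through the same stream, so results are
  bit-reproducible across runs and platforms with identical RNG state.

## Known limitations

* Cα-trace ensembles cannot use the minimal-heavy-atom contact criterion
  (no side chains) — the 8 Å Cα convention stands in.
* The ca-torsion helix criterion attributes each virtual torsion to two
  residues; isolated assignment at chain termini is impossible, so
  terminal residues are always coil.
* PDB numbering is taken verbatim from the file; insertion codes are
  rejected rather than interpreted, and only the first altloc is kept.
* The clustering scheme approximates fixed-radius tools in common use but
  is not claimed equivalent to any external implementation.
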