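---
title: "Restraint processing and ensemble validation: models, parameters and design"
author: "nmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint processing and ensemble validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrkit)
```

This vignette documents the scientific models behind `nmrkit`, the
parameters a user may want to change, the assumptions built into the
synthetic-data generators, and the design decisions taken where the
methodology leaves genuine freedom.

## NOE intensity-to-distance calibration

### Model

Cross-relaxation between protons makes the NOE cross-peak intensity fall
off approximately as the inverse sixth power of distance,

$$ I = c\,r^{-6}, $$

with a proportionality constant $c$ that depends on spectrometer, sample
and mixing time and must be calibrated per data set. Two effects make the
conversion approximate: intensities are also shaped by
distance-independent processes (longitudinal relaxation during the recycle
delay, spin diffusion during long mixing times), and a peak between proton
*groups* (methyls, unresolved pairs) sums the $r^{-6}$ contributions of
all proton pairs. The package therefore treats calibrated distances as
*upper bounds* with padding, not as target distances, and represents
methyls as first-class groups whose effective distance is
$r_\mathrm{eff} = \left(\sum_{ij} r_{ij}^{-6}\right)^{-1/6}$.

### Procedure

1. **Normalization** (`normalizeIntensities()`): each cross intensity is
   divided by the geometric mean of the diagonal intensities of its two
   spins. The geometric mean is symmetric in the two spins and makes the
   result invariant to a global rescaling of the spectrum; peaks lacking
   both diagonals are flagged and passed through.
2. **Anchor** (`calibrateConstant()`): $c = I_{\max} r_\mathrm{ref}^6$,
   where $I_{\max}$ is the strongest normalized amide–amide intensity and
   $r_\mathrm{ref}$ the shortest characteristic amide-proton distance
   class in β-sheets (below). Ties break deterministically by peak id.
3. **Inversion** (`boundsFromIntensities()`):
   $b = \mathrm{clamp}\!\left((c/I)^{1/6} + \mathrm{pad},\ 1.8,\ 7.0\right)$ Å.
   The transform is antitone in intensity by construction.
4. **Methyl classes** (`recalibrateFromModels()`): amide–methyl and
   methyl–methyl peaks are calibrated against a preliminary ensemble
   computed under uniform loose (7 Å) bounds:
   $b = \overline{r_\mathrm{eff}} + k\,\mathrm{sd}(r_\mathrm{eff})$ over
   the models, clamped to the same window.

### β-sheet distance classes

`sheetDistanceStats()` supplies the calibration anchor from geometry. On
ideal antiparallel sheets the cross-strand amide-proton distances fall
into two classes: the doubly hydrogen-bonded ("narrow") pairs at 3.4 Å
and the next-nearest register diagonals near 5.0 Å. On ideal parallel
sheets the NOE-range contacts are the register-diagonal pairs at 4.0 Å
and the sequential intra-strand pairs at 4.2 Å, while the registered
facing pairs sit at 5.0 Å. Distances are pooled per paired strand duo,
restricted to an NOE observability cutoff (`max_r`, default 5.5 Å), and
clustered by deterministic 1-D k-means (k = 2, centers initialized at the
extremes).

A known limitation: real parallel sheets are twisted, which staggers one
diagonal family down to roughly 3–4 Å; untwisted ideal geometry cannot
reproduce a ~3 Å parallel class (an exhaustive rigid-body multistart over
strand placements confirms the symmetric arrangement is the hydrogen-bond
optimum). The package reports what ideal geometry supports; surveys of
twisted crystal-structure sheets will see the shorter diagonal class that
ideal constructions lack.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pad` | 0.5 | Å | slack added to every inverted bound; absorbs the $r^{-6}$ approximation error |
| `floor`, `cap` | 1.8, 7.0 | Å | van der Waals contact and the loose-bound ceiling used for preliminary models |
| `k_sd` | 1 | – | spread multiplier for model-bootstrapped bounds |
| `max_r` | 5.5 | Å | amide NOE observability range for distance statistics |

The strongest-peak anchor has a max-statistics bias: with 20%
multiplicative intensity noise the estimated $c$ is biased high with a
median relative error near 25–30% (the padding and the upper-bound
semantics absorb this; the test suite checks the estimator against a
closed-form max-of-lognormals oracle).

## RDC alignment-tensor fitting

A bond unit vector $\mathbf{u}$ in a weakly aligned molecule experiences

$$ D = \mathbf{u}^\mathsf{T} \mathbf{A}\, \mathbf{u}
     = D_a\!\left[(3\cos^2\theta - 1)
       + \tfrac{3}{2} R \sin^2\theta\cos 2\phi\right], $$

where $\mathbf{A}$ is the symmetric traceless alignment tensor with
principal values $(2D_a,\ -D_a(1 + 3R/2),\ -D_a(1 - 3R/2))$, $D_a$ the
axial magnitude (Hz) and $R \in [0, 2/3]$ the rhombicity after ordering
$|A_{zz}| \ge |A_{yy}| \ge |A_{xx}|$. `fitTensorSVD()` solves the five
independent elements by SVD pseudoinverse of the direction-cosine design
matrix (rows $(u_y^2 - u_x^2,\ u_z^2 - u_x^2,\ 2u_xu_y,\ 2u_xu_z,\
2u_yu_z)$), requiring at least five records and warning above a condition
number of 10⁴. N–C′ couplings are rescaled to N–H-equivalent units by the
dipolar prefactor ratio $(\gamma_C/\gamma_H)(r_{NH}/r_{NC'})^3 \approx
0.113$ before use.

Design decisions:

* **Cross-validation by default.** N–C′ records are excluded from the fit
  and reported through a separate validation Q-factor, reflecting the
  practice of reserving one coupling type to validate structures rather
  than restrain them. `fit_types = c("NH", "NC")` overrides.
* **Per-model tensors.** `scoreModels()` fits each model independently —
  alignment is a property of the model, so filtering compares each
  model's own best fit.
* **Unweighted least squares by default**; `weighted = TRUE` scales rows
  by $1/\sigma$ when uncertainties are present.
* Amide protons are rebuilt from heavy atoms (bisector placement, 1.01 Å)
  when models carry no hydrogens.

The Q-factor is $\mathrm{rms}(D_\mathrm{obs} -
D_\mathrm{calc})/\mathrm{rms}(D_\mathrm{obs})$; it is undefined (NA) when
the observed rms vanishes.

## Chemical-shift disorder profiling

Secondary shifts are observed minus residue-type random-coil reference
values (a fixed package table of Wishart-type peptide values; Gly has no
Cβ, Pro no amide). Two per-residue summaries follow:

* **SSI** (`computeSSI()`): the sign of $\Delta\delta C_\beta -
  \Delta\delta C_\alpha$ (positive strand-like, negative helix-like),
  averaged over a sliding window (default 3, odd). Scores inside a 1 ppm
  deadband count as coil — the usual consensus convention, without which
  pure-noise data would produce spurious ±1/3 window votes. Residues with
  only one of the two carbons are scored from the available one.
* **RCI-S²** (`computeRCIS2()`): a weighted mean of absolute normalized
  secondary shifts (per-nucleus scales CA 2.5, CB 2.5, C′ 2.0, N 4.0,
  Hᴺ 0.6 ppm — typical full secondary-structure perturbations), smoothed
  over the window, inverted into a random-coil index
  $\mathrm{RCI} = 1/(1 + 40\,\bar{a})$ and mapped monotonically to
  $S^2 = \mathrm{clamp}(1 - 0.4\ln(1 + 17.7\,\mathrm{RCI}),\ 0,\ 1)$.
  Zero secondary shifts give $S^2 = 0$; plain helix offsets give ≈0.77 in
  the interior. Only the ordering properties (monotonicity, coil-low,
  structured-high) are contractual; the constants are package
  calibrations, not literature-traceable coefficients.

`trimFlexibleEnds()` removes terminal runs with $S^2$ below a threshold
(default 0.5, minimum run 3); interior residues are never removed, and an
all-flexible profile yields an empty interval with a warning rather than
an error. The defaults are conservative: the threshold sits halfway
between the coil and structured regimes of the mapping above, and the
minimum run prevents trimming on single noisy termini.

## Ensemble analysis

* **Superposition**: Kabsch SVD with reflection guard (determinant +1) and
  an explicit error on collinear/degenerate selections.
* **Convergence**: `ensembleRMSD()` reports the mean over all unordered
  model pairs, each pair independently superposed on the selection
  ("pairwise", the common NMR-ensemble convention), or the mean RMSD to an
  iteratively refined mean structure ("to-mean"). The two differ by about
  $\sqrt{2}$ for isotropic scatter; both are exposed because published
  convergence numbers rarely state which convention was used. Pairwise
  RMSD violates the triangle inequality and none is assumed.
* **Selection funnel**: `selectModels()` keeps the `n_energy` (default
  30) lowest-energy models of the pool, then ranks those by per-model RDC
  Q and by mean RMSD to the pool medoid, keeping the `n_final` (default
  10) best summed ranks with deterministic index tie-breaks. The medoid
  convergence metric makes the qualitative notion of "converged
  structures" concrete without fitting a reference structure.
* **Secondary structure**: hydrogen bonds by the Kabsch–Sander
  electrostatic energy (0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)
  kcal/mol, cutoff −0.5), three states only: helix from consecutive
  i→i+4 turns, strand from parallel/antiparallel bridge ladders, else
  coil. No 3₁₀/π/turn/bend distinction is attempted; a lone extended
  strand without a bridge partner is coil by definition. Chain breaks
  (C–N > 2.5 Å or numbering gaps) restart all patterns.
* **Topology**: strands are maximal strand runs; pairings come from
  bridge partners with orientation and register; ensembles are reduced by
  majority consensus over models.

## The synthetic-data module

The generators provide ground truth for every analysis stage:

* `makeIdealBackbone()` builds N, H, CA, C, O, CB (and idealized methyl
  groups for Ala/Val/Leu/Ile/Thr) from standard bond geometry by NeRF
  chain extension with canonical dihedrals — helix (−57, −47)°,
  antiparallel strand (−139, 135)°, parallel strand (−119, 113)°, coil
  (−120, 120)°. Residue 1's amide proton follows the periodic convention
  dihedral(C, CA, N, H) = φ + 180°.
* `makeSheet()` assembles strands into sheets by placing each successive
  strand with a Kabsch fit of its hydrogen-bonding atoms onto ideal
  N–H···O=C target positions (H···O 1.95 Å, N···O 2.95 Å along the donor
  and acceptor axes); a rigid-body optimizer with hydrogen-bond,
  acceptor-directionality and steric terms is the fallback when the
  analytic fit cannot realize the registry. The hydrogen-bonded parity of
  successive antiparallel strand pairs alternates with strand-length
  parity, since a residue's N–H can only donate to one neighbour strand.
  The returned pairing table is the oracle for topology and distance
  statistics. Default strands are poly-alanine: compact methyls keep
  ideal flat strands clash-free while still exercising the methyl NOE
  machinery.
* `simulateNOEPeaks()` emits $c\,r_\mathrm{eff}^{-6}$ intensities with
  unit-mean multiplicative lognormal noise (intensities are positive, so
  a lognormal is the simplest symmetric-in-log choice), plus diagonal
  intensities around a common scale; ground-truth effective distances
  ride along in the table's `truth` slot.
* `simulateRDCs()` applies the tensor forward model with additive
  Gaussian noise; `simulateShifts()` adds secondary-structure offsets
  (helix: +Cα, −Cβ; strand: −Cα, +Cβ) and Gaussian noise to the
  random-coil table; `perturbEnsemble()` displaces atoms with isotropic
  Gaussians whose 3-D rms magnitude is the stated sd (so the expected
  pairwise per-atom displacement between models is $\sqrt{2}\,$sd), and
  assigns a synthetic energy equal to the total squared displacement.

All generators are pure functions of their arguments and seed.

What the generators do **not** emulate — and hence what passing tests do
not establish about experimental data: spin diffusion and relaxation
leakage in NOE intensities (noise is independent per peak, not
distance-correlated), sheet twist (ideal strands are straight, so the
twist-staggered short parallel diagonal class is absent), sidechain
rotamer heterogeneity beyond fixed idealized rotamers, chemical-shift
referencing errors (offsets are zero-mean), alignment-medium distortions
of the molecule, and assignment ambiguity (all peaks come labelled with
their true atom groups).

## Numerical choices

* Distance-class clustering uses k-means with extreme-value initial
  centers, making it deterministic; duplicate-free degenerate inputs fall
  back to exact unique values.
* The SVD pseudoinverse truncates singular values below 10⁻¹² of the
  largest; the design-matrix condition number is reported.
* Superposition rejects selections whose second covariance singular value
  is below 10⁻⁸ of the first (collinearity).
* Tie-breaks (strongest peak, funnel ranks) always resolve by id/index so
  repeated runs are identical.
* Test and validation problem sizes — two- to five-strand sheets of 5–14
  residues per strand, ensembles of 3–100 models, 15–60 RDC vectors,
  20–100 random seeds per property — were chosen as the smallest sizes at
  which the checked statistics stabilize.

## Known limitations

* The $r^{-6}$ inversion ignores spin diffusion; bounds inherit the
  padding convention rather than modelling cross-relaxation pathways.
* RCI-S² constants are a monotone calibration, not a reimplementation of
  any published coefficient set; absolute values should not be compared
  against other software, only orderings and thresholds.
* Secondary-structure assignment is three-state and hydrogen-bond-only;
  it will under-call distorted helices that geometric methods recover.
* Ideal sheet geometry is untwisted; statistics that depend on sheet
  twist (notably the short parallel diagonal class) are not reproduced.
* The NMR-STAR reader handles the assigned-chemical-shift loop of v3
  files only; it is not a general STAR parser.
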