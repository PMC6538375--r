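# nmrkit

Restraint processing and validation for solution NMR structure
determination of small protein domains.

Solving the structure of a weakly structured or complex-stabilized domain
by NMR involves a data-processing layer between the spectra and the
structure-calculation engine: NOE cross-peak intensities must be converted
into upper distance bounds, residual dipolar couplings (RDCs) must be fit
to alignment tensors to validate and filter models, chemical shifts must be
turned into per-residue order and secondary-structure profiles to decide
which residues to model at all, and the final model pool must be reduced to
a converged, data-consistent ensemble. `nmrkit` implements that layer as a
tested R package, together with a synthetic-data module that generates
structures, intensities, couplings and shifts with known ground truth so
every stage can be verified without external downloads.

## The methods in brief

**NOE calibration.** NOE cross-peak intensity falls off with the inverse
sixth power of the inter-proton distance, *I* = *c·r*⁻⁶. Intensities are
first normalized by the geometric mean of their diagonal-peak intensities.
The proportionality constant is anchored on the strongest amide–amide
peak: *c* = *I*<sub>max</sub>·*r*<sub>ref</sub>⁶, with the reference
distance taken from the characteristic amide-proton distance classes of
β-sheets (≈3.4 Å for the doubly hydrogen-bonded antiparallel pair, with a
second class near 5 Å; computed from ideal generated sheet geometry by
`sheetDistanceStats()`). Bounds follow by inversion,
*b* = (*c*/*I*)^(1/6) + pad, clamped to [1.8, 7.0] Å. Amide–methyl and
methyl–methyl peaks are instead calibrated against preliminary models
computed under uniform loose 7 Å bounds: per peak,
*b* = mean(*r*<sub>eff</sub>) + *k*·sd(*r*<sub>eff</sub>) over the model
pool, where *r*<sub>eff</sub> = (Σ *r*⁻⁶)^(−1/6) sums over all group
proton pairs (methyls are first-class atom groups).

**RDC analysis.** Couplings obey *D* = **u**ᵀ**A**u for the bond unit
vector **u** and the symmetric traceless alignment tensor **A** (principal
values 2*D*<sub>a</sub>, −*D*<sub>a</sub>(1 ± 3R/2)). The five independent
tensor elements are fit by SVD of the direction-cosine design matrix;
agreement is scored by the Q-factor, rms(*D*<sub>obs</sub> −
*D*<sub>calc</sub>)/rms(*D*<sub>obs</sub>). N–C′ couplings are kept out of
the fit by default and reported as cross-validation.

**Shift profiling.** Secondary shifts Δδ = δ<sub>obs</sub> −
δ<sub>coil</sub> feed a secondary-structure index (sign consensus of
ΔδCβ − ΔδCα over a sliding window; +1 strand-like, −1 helix-like) and a
random-coil-index order parameter RCI-S² ∈ [0, 1] that increases
monotonically with the magnitude of the secondary shifts. Flexible termini
are trimmed below an S² threshold before structure calculation.

**Ensemble analysis.** Kabsch superposition, mean pairwise (or to-mean)
heavy-atom RMSD over core residues, a 100 → 30 → 10 model-selection funnel
(energy cut, then RDC-Q and medoid-convergence ranking), hydrogen-bond
(Kabsch–Sander energy) secondary-structure assignment and β-sheet topology
extraction with strand pairing and register.

## Worked example

```r
library(nmrkit)

sheet <- makeSheet(n_strands = 2, strand_len = 8, topology = "antiparallel")
stats <- sheetDistanceStats(sheet$model, sheet$pairing, "antiparallel")
stats
#> SheetDistanceStats (antiparallel): classes 3.43, 5.02 A (n = 14)

peaks <- simulateNOEPeaks(sheet$model, c = 729, max_r = 5.5,
                          noise_cv = 0.1, seed = 42)
peaks
#> NOEPeakTable: 168 peaks (amide-amide: 28, amide-methyl: 86, methyl-methyl: 54)

norm <- normalizeIntensities(peaks)
cal  <- calibrateConstant(norm, stats)
cal
#> CalibrationResult: c = 980.1, reference peak 102 at 3.43 A, pad 0.50 A

bounds <- boundsFromIntensities(norm, cal, classes = "amide-amide")
bounds
#> RestraintList: 28 restraints, bounds 3.9-5.9 A

tensor <- AlignmentTensor(Da = 10, rhombicity = 0.3, euler = c(20, 40, 60))
rdcs <- simulateRDCs(sheet$model, tensor, types = c("NH", "NC"),
                     noise_sd = 1, seed = 43)
fit <- fitTensorSVD(sheet$model, rdcs)
fit
#> RDCFitReport: 16/30 records used, Q = 0.1657, rms = 0.653 Hz

ens <- perturbEnsemble(sheet$model, n_models = 10, core_sd = 0.3, seed = 44)
ensembleRMSD(ens, selection = "all")$mean_rmsd
#> [1] 0.4259529
```

The distance classes are the two characteristic amide-proton separations
of an ideal antiparallel sheet (hydrogen-bonded pairs at 3.43 Å,
next-nearest diagonals near 5 Å). The calibration constant recovered from
10%-noisy intensities (980 vs the true 729) reflects the max-statistics
bias of the strongest-peak anchor, which is why bounds are upper limits
with padding rather than target distances. The RDC fit uses only the 16 NH
couplings; the 14 N–C′ couplings are held out for validation. The mean
pairwise RMSD of the perturbed ensemble, 0.43 Å, is √2 × 0.3 Å as expected
for independent Gaussian displacements.

A command-line front-end (`inst/exec/nmrkit`, or `runCLI()` from R)
exposes each stage (`simulate`, `shift-profile`, `calibrate-noe`,
`fit-rdc`, `select-models`, `ensemble-stats`) and an end-to-end `demo`
that is byte-reproducible for a fixed `--seed`.

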