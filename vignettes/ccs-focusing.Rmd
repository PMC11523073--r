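---
title: "CCS knowledge-based conformational focusing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCS knowledge-based conformational focusing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsfocus)
```

## The problem

Gas-phase structure prediction for flexible lipids compares *in silico*
conformer ensembles against collision cross sections (CCS) measured by
ion-mobility mass spectrometry. For a fatty acid with ~14 rotatable bonds the
conformational space is enormous, and the expensive step — quantum-chemical
geometry optimization of candidate conformers — scales with the number of
conformers carried forward. Most of a raw ensemble is "deadwood": conformers
whose gas-phase size is nowhere near the measured CCS and which will never
become the experimental structure.

`ccsfocus` implements a CCS knowledge-based filter that removes that deadwood
*before* the expensive stage. A fast regressor predicts the CCS of every raw
conformer from five cheap molecular descriptors; conformers whose predicted
CCS falls outside a band around a user-supplied reference CCS (typically the
experimental value) are discarded. The filter is a post-processing step that
composes with any conformer generator.

## The model

### Descriptors

Each conformer of a lipid [M−H]⁻ anion is summarized by five molecular-level
descriptors, chosen to be cheap enough for batches of 10⁴ conformers:

| descriptor | meaning | units |
|---|---|---|
| `mz` | mass-to-charge of the deprotonated anion | Da |
| `d_het_max` | farthest heteroatom from the center of mass | Å |
| `d_atom_max` | farthest atom from the center of mass | Å |
| `n_het` | number of heteroatoms (≠ C, H) | count |
| `msa` | molecular surface area | Å² |

Conventions the package fixes (they are deliberately pinned so results are
reproducible without environment-dependent constants):

* **Masses** are monoisotopic, from a single embedded table
  (`element_table()`); the center of mass uses the same masses.
* **m/z** is the neutral monoisotopic mass minus the proton mass 1.00728 Da
  (electron mass neglected). Input geometries are assumed to already be the
  deprotonated species, so one H is added back to form the neutral formula;
  `geometry_is_neutral = TRUE` disables that correction.
* **Heteroatom** means any element other than carbon and hydrogen.
* **MSA** is a solvent-accessible surface area (Shrake–Rupley): each atom
  carries a deterministic golden-spiral point set (960 points by default) on
  a sphere of radius `vdw + 1.4 Å`; the exposed fraction times the sphere
  area is summed. Van der Waals radii are Bondi values. The golden-spiral
  construction is seed-free, so the descriptor is exactly reproducible; its
  only noise is the ~1% orientation dependence of finite point sampling.
* `d_het_max` is defined as 0 for a molecule with no heteroatoms.

### Regressor

The CCS regressor is a fully connected feed-forward network: an input node
per descriptor, six hidden layers (default widths 64-128-128-64-32-16,
activations alternating relu/gelu), and one linear output node. It is
trained with Adam on a mean-absolute-error loss, with a seeded 80/20
train/validation split of conformer instances. Because the five descriptors
mix units (Da, Å, counts, Å²), features are z-scored by training-split
statistics; labels are z-scored internally for optimizer conditioning and
predictions are transformed back to Å². Early stopping watches the held-out
MAE (patience 40 epochs) and restores the best-epoch weights. Training is
bit-reproducible given the config seed.

The hidden-layer widths and learning hyperparameters are package defaults,
exposed in `ccs_regressor_config()`; nothing downstream depends on their
exact values. A `feature_mask` can drop any descriptor — necessary whenever
a descriptor is constant over the training domain (a zero-variance feature
is an error, not a silent pass-through), and useful for ablation.
`group_split = TRUE` splits by species instead of by instance, preventing
conformers of one species from straddling the split; the instance split is
the default.

### The filter band

The band around the user CCS is set semiautonomously from the regressor's
batch error statistics at its latest evaluation. With per-prediction
fractional errors \(e_i = |CCS_{pred,i} - CCS_{label,i}| / CCS_{label,i}\),

$$\bar e = \frac{1}{N}\sum_i e_i, \qquad
  \sigma_{\bar e} = \mathrm{sd}(e_i)/\sqrt{N},$$

$$\mathrm{upper} = CCS_{user}\,(1 + \bar e + \sigma_{\bar e}), \qquad
  \mathrm{lower} = CCS_{user}\,(1 - \bar e - \sigma_{\bar e}).$$

The band is closed at both ends, collapses to a point for a perfect model,
and widens linearly in \(\bar e + \sigma_{\bar e}\). "Standard error" here
is the standard error of the mean (sd/√N), not the sd. Each of the four
quantities lives in its own function (`error_statistics()`,
`filter_bounds()`) so an alternative convention — a multiple of the SEM, or
percentile errors — can be swapped in one place. By default the statistics
come from the model's held-out evaluation (`model$error_stats`); a
user-supplied summary via `summary_error_stats()` overrides them.

An optional capacity limit keeps only the k retained conformers whose
predictions are nearest the user CCS (ties by input order). Filtering
preserves input order and annotates survivors with `pred_ccs`.

### Downstream ensemble processing

After focusing, `run_ccsf_workflow()` mirrors the standard
structure-prediction pipeline:

1. **Representative clustering** — greedy leader clustering under Kabsch
   RMSD: scanning in input order, a conformer founds a new cluster iff its
   RMSD to every existing representative exceeds the threshold (default
   1.0 Å). This preserves the role of graph-based clustering tools (reduce
   hundreds of conformers to a practical QM workload) with a deliberately
   simple, fully specified algorithm. Hydrogens are included by default
   (`include_hydrogens = FALSE` excludes them).
2. **Energies** — the pipeline never runs quantum chemistry. Relative
   energies (kcal/mol) enter either as metadata on the XYZ comment line or
   through a pluggable `energy_provider` function; hartree input can be
   converted (× 627.5095).
3. **Candidate selection** — the lowest-energy conformer, ties broken by
   input order.
4. **Boltzmann-weighted CCS** — weights
   \(w_i \propto \exp(-(E_i - E_{min})/RT)\) with
   R = 0.0019872 kcal mol⁻¹ K⁻¹ at a default 298.15 K (no temperature is
   canonical for gas-phase ensemble averaging; 298.15 K is the conventional
   choice). The minimum-shift makes the exponentials numerically safe and
   the weights offset-invariant. The Boltzmann average is taken over all
   representatives, not only low-energy members.
5. **Scoring** — percent CCS error, always with the experimental value in
   the denominator, rounded to two decimals in result tables, with a pass
   flag at the 3% threshold conventionally used to absorb IM-MS calibration
   and Mason–Schamp uncertainties. Table means are means of the rounded
   rows, matching how such tables are conventionally reported.

When the band captures nothing, the workflow reports
`"no viable conformers"` instead of failing — the informative outcome when a
model extrapolates outside its training domain.

## The synthetic data generator

Real training data for this problem requires a conformer generator, DFT
optimization and a trajectory-method CCS code. To make every stage testable
on a desktop, `synthetic_spec()` + `generate_ensemble()` build fatty-acid
like [M−H]⁻ conformers and label them with a deterministic geometric CCS
oracle:

* **Geometry.** Carboxylate head (two 1.26 Å C–O bonds at 117°, no acidic
  hydrogen), a zig-zag backbone (C–C 1.54 Å, C=C 1.33 Å, angles 111.5°/120°
  for sp³/sp²), backbone dihedrals drawn trans/gauche± with probabilities
  0.6/0.2/0.2 (a textbook rotamer distribution for flexible alkyl chains)
  plus ±10° uniform jitter, double-bond torsions fixed at 0° (cis) or 180°
  (trans), and geometrically placed hydrogens. Anything with a nonbonded
  contact under 1.0 Å is rejected and resampled. A conformer is a
  deterministic function of `(seed, index)`.
* **Labels.** `pa_ccs()` is an orientation-averaged hard-sphere projection
  area: over a seeded stream of uniformly random orientations (Shoemake
  quaternions from a xorshift64* generator, so streams are identical across
  platforms), atoms with radius `vdw + 1.4 Å` are projected and the
  union-of-disks area is measured on a grid (0.2 Å default) whose origin is
  dithered per orientation to cancel discretization bias. This is a
  projection approximation, not a trajectory method: absolute values differ
  systematically from experimental N₂ CCS (our synthetic C18–C22 labels run
  ~120–185 Å²), but the geometry→CCS mapping that the filter relies on is
  preserved. The oracle is never compared to experimental values.
* **Energies.** Optionally,
  `energy = energy_scale × (label_ccs − min label_ccs)` kcal/mol, a
  documented compactness proxy that makes the most compact conformer the
  energy minimum. It exists to exercise candidate selection and Boltzmann
  averaging, not to model a force field.

The canonical study mix (`synthetic_species_grid()`,
`synthetic_training_set()`) spans 18–22 carbons and 0–6 double bonds at
common Δ positions, split evenly across ten species. Because every synthetic
species is a plain free fatty acid, `n_het` is constant (2) over this
domain; the canonical synthetic training therefore masks it, which is the
intended use of the feature mask. What passing the synthetic end-to-end test
shows is that the pipeline — descriptors, regressor, band, filter — recovers
a smooth geometric CCS oracle to about 1% held-out error at n = 5000; it
does *not* show that the trained weights transfer to real trajectory-method
labels, real charge distributions, or lipid classes outside the synthetic
family (rings, oxygenated chains).

## Numerical choices and degenerate inputs

* XYZ metadata rides as whitespace-separated `key=value` tokens (`id`,
  `charge`, `energy`, `ccs`) on the comment line — a convention this package
  owns; coordinates are written at six decimals and round-trip to ≤ 1e-6 Å.
* Formula consistency across frames is enforced at construction; a
  violating frame is an error naming the frame.
* Kabsch RMSD computes the optimal rotation from the SVD of the covariance
  matrix (determinant-corrected to exclude reflections) and evaluates the
  RMSD on the rotated coordinates directly, which keeps rigid-motion images
  at ~1e-15 instead of the ~1e-7 cancellation noise of the eigenvalue
  shortcut.
* The band is inclusive at both ends (an arbitrary but documented choice);
  `mean_error + sem_error ≥ 1` is rejected rather than producing a
  nonpositive lower bound.
* A single-prediction batch has `sem_error = 0`.
* Capacity ties (equal |pred − user|) resolve to input order via a stable
  sort.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately desk-friendly sizes: the
synthetic recovery study trains on 5000 conformers across ten species
(three seeds, majority criterion: held-out mean % error ≤ 3% and R² ≥ 0.9 —
the regime in which the filter band is meaningfully narrow), randomized
filter checks use 1000 trials, and the demonstration workflow focuses a
2000-conformer ensemble. The benchmark CCS tables shipped in
`inst/extdata/` are re-scored cell by cell from their experimental and
calculated CCS columns; one published aggregate (the large-lipid
standard-method average) is not reproducible from its own rows (26.47 vs
the printed 26.44, under any rounding order) and is documented rather than
asserted.

## Known limitations

* The projection-approximation oracle ignores ion–gas interaction
  potentials; synthetic CCS values are systematically smaller than
  trajectory-method N₂ values for the same geometry.
* The synthetic generator covers acyclic mono-carboxylate chains only — no
  rings, hydroxyl/oxo substituents, positive-mode adducts, or real
  stereochemistry.
* The symmetric multiplicative band is one reconstruction of the filter
  rule; asymmetric or percentile-based bands are out of scope but can be
  swapped behind `filter_bounds()`.
* Greedy leader clustering is order-dependent by design (deterministic,
  cheap); it is a stand-in for graph-based clustering, preserving the
  workload-reduction role rather than any particular cluster topology.
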