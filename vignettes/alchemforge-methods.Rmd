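---
title: "Methods: disagreement-driven sampling, composite CBS energies, and the dataset layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disagreement-driven sampling, composite CBS energies, and the dataset layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemforge)
```

## The acquisition signal

An ensemble of interatomic potentials trained on the same data with
different seeds or resamples agrees closely where the training set is dense
and drifts apart where it is not. `alchemforge` quantifies this with

$$\rho(x) \;=\; \frac{\sigma_{\mathrm{pop}}\!\left(E_1(x),\dots,E_k(x)\right)}{\sqrt{N_a}}$$

where the $E_m$ are the member energies converted to kcal/mol and $N_a$ is
the atom count of $x$. Three conventions are fixed deliberately:

* **Population, not sample, standard deviation.** The members are the whole
  ensemble, not a sample from a larger one; $\rho = 0$ then holds exactly
  when all members agree, which several degenerate-case contracts rely on.
* **Proportionality constant 1, units kcal/mol/√atom.** Disagreement
  measures of this family are defined up to a constant; fixing it at 1
  makes thresholds directly interpretable as per-√atom energy spreads.
  Thresholds are therefore configuration, never constants of the package,
  and the shipped defaults (1.0) are arbitrary placeholders.
* **√N normalization.** Energy variance grows roughly extensively with
  system size; dividing by $\sqrt{N_a}$ keeps one threshold meaningful
  across molecules of different sizes.

Batch selection (`select_high_rho`) is a strict filter, $\rho > t$,
preserving candidate order, so selections at threshold $t_2 \ge t_1$ are
always nested inside selections at $t_1$.

## Samplers

All samplers consume a potential-ensemble contract — any object returning
per-member energies (Ha) and forces (Ha/Å) for a conformation — and emit
`selection_batch` objects carrying $\rho$ and provenance (sampler name,
parent structure, seed, halt step). Full reproducibility from the seed is a
tested invariant.

### Molecular dynamics

Langevin dynamics with the BAOAB splitting: half kick, half drift, exact
Ornstein–Uhlenbeck velocity refresh, half drift, half kick. With zero
friction the OU step is skipped entirely and one step is exactly velocity
Verlet, which the tests exploit as the zero-coupling limit. Parameters: time
step 0.5 fs, friction 0.02 fs⁻¹, simulation temperature drawn uniformly from
50–800 K, $\rho$ checked every 5 steps, halt at the first above-threshold
check. The trajectory cap (`max_steps`, default 10 000) is this package's
choice; an uncapped gated trajectory has no termination guarantee when the
ensemble never disagrees. Masses are in amu, coordinates in Å, time in fs;
the single conversion constant (1 amu Å²/fs² = 3.80880 Ha) and
$k_B = 3.166811563\times10^{-6}$ Ha/K live in one internal file. Kinetic
temperature counts all $3N_a$ degrees of freedom without center-of-mass
removal — with the thermostat coupled to every component this is the
quantity equipartition controls.

### Normal-mode sampling

Modes are stored as Cartesian displacement shapes $d_i$ that are
mass-orthonormal ($d_i^{\mathsf T} M d_j = \delta_{ij}$), with force
constants $k_i$ the mass-weighted Hessian eigenvalues; the cross terms
$d_i^{\mathsf T} H d_j$ then vanish, so the harmonic energy of a displacement
$\sum_i q_i d_i$ is exactly $\sum_i \tfrac12 k_i q_i^2$. Each sampled
conformer draws, per mode, $c_i \sim U[0,1)$ and a random sign, and
displaces by $q_i = \pm\sqrt{2 c_i k T / k_i}$. Consequences used as
oracles: every per-mode energy is below $kT$, the mean total harmonic energy
is $n_{\text{modes}}\,kT/2$, and $T = 0$ reproduces the reference exactly.
The sampling temperature (default 300 K) and the number of conformers per
molecule are configuration; the underlying displacement convention is the
package's concrete choice for the loosely specified "random distance along
each normal mode" family of schemes.

Finite-difference Hessians (central differences of analytic forces, step
0.005 Å) are mass-weighted and diagonalized; modes with eigenvalue below
`drop_tol = 1e-3` Ha/(amu Å²) are discarded. The cutoff sits two orders of
magnitude below genuine vibrational eigenvalues of the surrogate potentials
(0.1–10 in these units) and one above the rigid-translation/rotation
contamination observed for finite-difference Hessians at geometries
optimized to the default force tolerance (~1e-4).

### Dimer sampling

Boxes are rectangular with edges drawn uniformly from 20–30 Å. Molecules
are drawn from the pool with probability ∝ $n_{\text{heavy}}^{-p}$
(default $p = 1$; the direction of the small-molecule bias is the
established protocol, the power-law form is this package's choice) until a
target atom density — drawn uniformly from 0.005–0.02 atoms/Å³, a range
chosen to put roughly 5–40 small molecules in such a box — is met. Each
molecule is placed rigidly with a uniform random rotation (random unit
quaternion) and uniform position, rejected while any minimum-image distance
to already-placed atoms is below 1.5 Å, and kept whole (unwrapped): the
cell enters only through the minimum-image metric. After 100 Langevin steps
at 50–600 K the box is decomposed into one dimer per molecule pair whose
minimum-image contact distance is within 6 Å; the partner monomer is
shifted by the lattice vector realizing that contact, and the dimer carries
no cell. Whether the original box dynamics used periodic forces is not
specified in the protocols this follows; the surrogate applies minimum-image
pair forces, which is documented behavior of the default, not a claim about
the original runs.

### Torsion sampling

A structure provider (`function(smiles)`) supplies the 3-D geometry and the
rotatable-bond list; a toy-geometry fixture provider and an OpenBabel-CLI
provider ship with the package, and any cheminformatics toolkit can be
plugged in. The scan starts at the dihedral of the optimized geometry and
proceeds in +10° increments for 36 steps — starting angle and direction are
unspecified upstream and fixed here. Each step is a constrained
minimization: forces are projected off the analytic dihedral gradient,
steepest-descent steps are taken with backtracking, and the constraint is
re-enforced exactly after every step by rigid rotation of the rotating-side
atoms about the bond axis, so the returned dihedral is exact to floating
point (the contract requires 0.1°). $\rho$ is measured at every scan point;
on the first exceedance the scan halts and the halted structure is
perturbed along the normal modes of the ensemble-mean potential (central
finite differences, step 0.005 Å) to produce exactly four batch entries.
The halted structure itself is never returned — the goal is to sample the
valley's surroundings, not the path through it. The perturbation magnitude
("slightly perturbed" upstream) is set by a temperature-equivalent scale,
default 50 K, as configuration.

## Composite CBS energies

The composite total energy is assembled from six components:

$$E = \mathrm{Extrap}(3/4,\mathrm{HF}) + \mathrm{Extrap}(3/4,\mathrm{MP2}) - E(3,\mathrm{MP2}) + E(3,\mathrm{NPNO}) + E(2,\mathrm{TPNO}) - E(2,\mathrm{NPNO})$$

with the exponential HF form (α = 5.46) and the inverse-power correlation
form (β = 3.05), both optimized for cc-pV[TQ]Z extrapolation; cardinals
2/3/4 map to cc-pVDZ/TZ/QZ. The MP2 and coupled-cluster terms are read as
*correlation* energies: the dataset layout stores them under
`*.corr_energy` keys, and the HF total is handled by its own extrapolation —
reading them as totals would double-count the HF contribution. Both
extrapolations are affine in their energy arguments and approach the
cardinal-4 value as their exponent grows; both identities are tested, and
1000 random component sets are compared against a 50-digit-arithmetic
reference to 1e-12 relative. The public API is double precision throughout.

## Dataset layout and the key-filtered loader

One HDF5 group per isomer; dataset names are the fixed property key strings
with fixed dtypes (energies float64, geometric and per-atom properties
float32, atomic numbers uint8) and shapes with leading conformer dimension.
Arrays are transposed on write so the on-disk C-order shapes match the
documented `(Nc, Na, 3)`-style layout as seen from NumPy/h5py — files are
interoperable, not merely R-internal. Design choices the layout
specification leaves open, fixed here and documented:

* **Missing values are NaN-padded**, never ragged: a property absent for
  some conformers of a group stores `NaN` rows, and the loader filters on
  `NaN`. This matches the observable behavior of the published loaders
  (requesting more keys can only shrink the result — a tested monotonicity
  invariant).
* **Group naming** is `<stoichiometry>_<index>` (e.g. `C2H6O_00001`).
* **Units are stored as documented** (Ha, Å, Ha/Å, e·Å, a.u.); no
  conversion happens at the I/O layer.
* **Quadrupoles** store six components in the order (xx, yy, zz, xy, xz,
  yz); only the count is fixed upstream.

`validate_schema` reports every dtype/shape/key deviation with its group
and key; `iter_data_buckets` always includes `coordinates` and
`atomic_numbers`, preserves conformer order, and silently skips groups left
empty by the filter.

## Active learning

`al_iteration` is the outer loop: fit ensemble → run samplers → label the
deduplicated union → append → advance. Identity is the provenance id, so no
conformation is ever labeled twice; labeler failures drop the structure,
log the event, and continue. `ccx_subset_selection` implements high-level
re-labeling: a uniform initial draw (default fraction 0.05 — the original
campaigns' initial subset size is unpublished) followed by four
disagreement-driven cycles, each selecting `rho > threshold` from the
remainder, optionally capped. All selections are logged with their $\rho$
at selection time so runs can be audited by replay.

The shipped trainer is a bootstrap-ensembled Gaussian kernel ridge
regressor over a user-supplied featurizer — adequate for the toy-surface
recovery experiments, and deliberately not a production interatomic
potential (default ensemble size 8, configurable; the original ensemble
counts are unpublished).

## Surrogates and fixtures: what they do and do not emulate

The surrogate ensemble is an all-pairs Morse base potential (well depth
0.15 Ha, steepness 2 Å⁻¹, equilibrium at the covalent-radius sum) plus a
per-member term $A\, z_m\, u(x)$ with centered fixed normal draws $z_m$, so
the ensemble mean is exactly the base and $\rho = A\,\sigma(z)\,u(x)
\cdot 627.5/\sqrt{N_a}$ — exactly linear in the amplitude $A$. The
disagreement field $u$ is a geometry-wide Morse shape, a Gaussian-damped
stretched-bond measure, or a Gaussian window in one dihedral; all are
functions of internal coordinates, making $\rho$ rigid-motion invariant,
and all member forces are analytic (tested against finite differences at
1e-6). Energies sit at chemically plausible magnitudes (~0.01–0.1 Ha
relative) so kcal/mol thresholds are meaningful.

What passing tests therefore show: the *machinery* — gating, halting,
selection, bookkeeping, extrapolation, I/O — behaves exactly as specified
on smooth, cheap, controllable potentials. What they do not show: anything
about real ML-potential training dynamics, real disagreement landscapes,
conformational preferences of real molecules, or electronic-structure
accuracy. The HDF5 fixtures plant availability patterns and keep all
single-precision values on a 1/1024 grid so bitwise round-trip claims are
decidable; planted loader counts stand in for the published file's counts,
which would require a multi-gigabyte download and are not asserted here.

## Problem sizes and numerical settings used by the test suite

The suite runs on one CPU in about a minute: thermostat averages over
1.2–1.5×10⁵ Langevin steps of a single harmonic particle (5% tolerance on
the mean kinetic temperature, against an O(dt²) splitting bias of under 1%
at 0.5 fs), 10⁴ normal-mode draws for the equipartition mean (5%), 50
random boxes for the brute-force dimer audits, 1000 random component sets
for the extended-precision CBS comparison, and ten seeded repeats of the
active-learning-vs-random comparison on a three-well 2-D surface (300-point
candidate pool, 8 + 5×10 labels, 25×25 held-out grid, win criterion on the
maximum held-out error of the ensemble mean in at least 8 of 10 repeats).

## Known limitations

* Geometry optimization is projected steepest descent with backtracking —
  robust and dependency-free, but slow near flat minima; `opt_max_iter`
  caps the cost and the `"converged"` attribute reports truncation.
* The torsion constraint projects only the scanned dihedral; other internal
  coordinates relax freely, so strongly coupled torsions can shift during a
  scan.
* Bond perception is a covalent-radius rule (factor 1.3); it has no notion
  of bond order or aromaticity and exists for environment labels and
  rotatable-bond enumeration, not general cheminformatics. The upstream
  protocols delegate this to external toolkits without stating a rule.
* `iter_data_buckets` reads whole groups into memory; it is a filtered
  loader, not an out-of-core streamer.
* The 2-D embedding hook defaults to principal axes; nonlinear embeddings
  (e.g. t-SNE variants) are delegated to any user-supplied embedder.
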