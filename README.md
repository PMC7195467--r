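# alchemforge

Tooling for building quantum-chemistry training datasets by active learning.
Ensembles of interatomic potentials disagree most where their training data
are thinnest; `alchemforge` turns that disagreement into an acquisition
signal, drives four conformer-sampling strategies with it, assembles
coupled-cluster-quality composite energies from cheaper components, and
reads/writes the conformer-property HDF5 layout used by large public
molecular datasets.

It is aimed at researchers who train machine-learning potentials for organic
(H/C/N/O) molecules and need to grow, label, audit or repackage their
datasets. Every pipeline stage runs against cheap analytic surrogate
potentials, so the full machinery is testable on a laptop with no
electronic-structure engine.

## What it implements

**Disagreement measure.** For an ensemble of k potentials predicting
energies E_1..E_k (Ha) for a structure with N_a atoms,

    rho = sigma_pop(E_1..E_k, in kcal/mol) / sqrt(N_a)

the population standard deviation normalized by the square root of the atom
count (kcal/mol/sqrt(atom)). Structures with `rho` above a configurable
threshold are collected into selection batches for labeling.

**Samplers.**

* *Molecular dynamics* — Langevin (BAOAB) dynamics at a random temperature
  in 50–800 K (0.5 fs step, 0.02 fs⁻¹ friction), `rho` checked every 5
  steps; the trajectory halts at the first above-threshold structure.
* *Normal modes* — random signed displacements along harmonic modes, each
  mode receiving an energy `c·kT` with `c ~ U[0,1)`; above-threshold
  conformers are kept.
* *Dimers* — random 20–30 Å periodic boxes packed with small-molecule-biased
  draws (placement clash limit 1.5 Å), 100 MD steps at 50–600 K, then
  decomposition into all molecule pairs in minimum-image contact within
  6 Å.
* *Torsions* — relaxed dihedral scans in 10° increments over the full 36-step
  profile; the scan halts where `rho` exceeds its threshold and contributes
  four normal-mode perturbations of the halted structure.

**Composite CBS energies.** The complete-basis-set composite

    E = Extrap(3/4, HF) + Extrap(3/4, MP2corr) − MP2corr(3)
        + NPNO-CCSD(T)corr(3) + TPNO-CCSD(T)corr(2) − NPNO-CCSD(T)corr(2)

with the Hartree–Fock extrapolation
`(e^{−α√4}·E3 − e^{−α√3}·E4) / (e^{−α√4} − e^{−α√3})` (α = 5.46) and the
correlation extrapolation `(4^β·E4 − 3^β·E3) / (4^β − 3^β)` (β = 3.05),
cardinals 2/3/4 = cc-pVDZ/TZ/QZ.

**Dataset files.** One HDF5 group per isomer, one dataset per property with
fixed key strings, shapes and dtypes (`wb97x_dz.energy` float64 (Nc),
`coordinates` float32 (Nc,Na,3), `atomic_numbers` uint8 (Na), …); `NaN`
marks a per-conformer missing value, and `iter_data_buckets(path, keys)`
returns, per group, only the conformers carrying every requested key.

**Diversity analysis.** Per-element linear energy baselines and residual
histograms (1 mHa bins), atom-count histograms, bonded-neighbor environment
labels (ethanol's carbons: `HHHC` and `HHCO`), 384-dimensional atomic
environment vectors for H/C/N/O, and a pluggable 2-D embedding hook.

**Active-learning loops.** `al_iteration()` runs train → sample → label →
append with never-label-twice bookkeeping and JSON-lines audit logs;
`ccx_subset_selection()` re-labels a dataset subset at a higher level of
theory over an initial uniform draw plus four disagreement-driven cycles.

## Worked example

```r
library(alchemforge)

# a surrogate ensemble whose members disagree where bonds stretch
ens <- make_surrogate_ensemble(k = 4, amplitude = 0.02,
                               localization = "stretch", seed = 7)
eth <- make_toy_molecules("ethanol")[[1]]
ensemble_rho(ens, eth)
#> [1] 0.6278425

# disagreement-gated MD: halts at the first check with rho > 0.8
batch <- md_sample(eth, ens, md_config(rho_threshold = 0.8,
                                       max_steps = 2000), seed = 4)
batch
#> <selection_batch> 1 structure(s)
#>   rho: 1.058

# composite CBS energy from tabulated components
extrap_hf(-76.00, -76.06, alpha = 5.46)
#> [1] -76.07808
```

`ensemble_rho` is in kcal/mol/sqrt(atom): 0.63 means the four members'
energies for ethanol spread by about 1.9 kcal/mol (0.63 × √9). The MD
sampler stopped at the first structure whose spread exceeded the 0.8
threshold — that structure, with its provenance (sampler, seed, step,
temperature), is what would be sent for quantum-chemistry labeling. The
extrapolated Hartree–Fock energy lies below both finite-basis inputs, as a
basis-set limit should.

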