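# reactfactors

Post-processing toolkit for quantum-chemistry studies of
methyl-coenzyme M reductase (MCR), its nickel corphinoid cofactor F430
and the cofactor's biosynthetic precursors. The package computes the
*reactivity factors* such studies reason with — it consumes geometries,
Hessians, energies and charge/orbital tables from electronic-structure
calculations and never performs quantum chemistry itself.

It is written for computational (bio)inorganic chemists who have cluster-model
outputs in hand and want the derived analysis to be scripted, testable and
reproducible:

* **Normal modes with frozen-atom projection** — mass-weighted
  diagonalization after zeroing the fixed framework atoms of a cluster
  model, giving the `3n − 24` / `3n − 25` mode counting of an 8-atom
  frozen framework for minima / transition states.
* **Kinetic energy distribution (KED)** of any mode:
  `KED_iα = m_i|r_iα|² / Σ_k m_k|r_kα|²`, the fraction of a mode's kinetic
  energy on atom *i*; `fragment_ked()` gives e.g. the KED_CH3 of the
  nascent methyl radical in the reactive (imaginary) mode of the S–CH3
  cleavage transition state.
* **RRHO thermochemistry** — `G = E_el + ZPVE + [pV − RT ln Q]` with a
  frozen-cluster regime (projected vibrational DOF only) and a
  free-molecule regime (Sackur–Tetrode translations, rigid-rotor
  rotations), and **reduction potentials**
  `E° = (G_ox − G_red) − E°_abs(ref)` against an absolute electrode
  reference (NHE, 4.28 eV, by default).
* **Thermodynamic-cycle decomposition** of the rate-determining reductive
  S–CH3 cleavage (homolysis + electron transfer + Ni–S bond formation)
  and of the S–S coupling step, with exact closure checks, plus the
  BEP-type ΔG‡/ΔG₀ regression and leg-vs-total correlation slopes.
* **Ligand polarization** `P(q_P) = Σ_i |q_i(q_P) − q_i(0)|` from
  atomic-charge response tables probed by a central point charge, and its
  slope (fixed-zero and free-intercept fits).
* **Scalar descriptors** — the σ*(S–CH3) carbon fraction
  `F_CH3 = p_C/(p_C + p_S)`, differential Coulombic metal–ligand
  interactions, and cross-model trend fits (Ni–N vs Ni–S distances, bond
  orders, KED vs F_CH3).
* **Synthetic-data generators** (`gen_*`) that emulate all of the above
  inputs with known truths, so the entire pipeline is testable without
  electronic-structure software.

## Worked example

A synthetic five-model series (A–E, emulating a cofactor maturation
study) is generated with known truths, then analysed with the same
functions one would apply to real ledgers:

```r
library(reactfactors)

series <- gen_model_series(series_spec(), seed = 42)

# late transition states => barrier tracks driving force ~1:1
bep_regression(series$energetics)[c("slope", "r")]
#> $slope
#> [1] 1.04252
#> $r
#> [1] 0.9975578

# step-1 cycle of the last model, built from its species ledger
led <- as.data.frame(series$ledger)
build_step1_cycle(fe_ledger(led[led$model == "E", ]))
#> <thermo_cycle> step1: total 3.000 kcal/mol
#>   dG'_cleavage         79.200
#>   dG'_ET              -19.840
#>   dG'_NiS             -56.360

# which factor dominates the trend? Ni-S leg slope vs ET leg slope
cycles <- lapply(series$legs$model, function(m)
  build_step1_cycle(fe_ledger(led[led$model == m, ])))
leg_correlations(cycles, series$potentials$E0)
#>   quantity slope intercept  r
#> 1      NiS   2.8    -64.76  1
#> 2       ET  -1.8    -14.44 -1
#> 3 cleavage   0.0     79.20 NA
#> 4       E0  -1.8      0.12 -1

# ligand polarization slope recovered from a noisy charge-response table
crA <- gen_charge_response(25, preset = "A", noise_sd = 0.005, seed = 7)
polarization_slope(polarization_curve(crA))$m
#> [1] 1.336862

# carbon fraction of the sigma*(S-CH3) orbital from printed percentages
f_ch3(p_C = 43, p_S = 19)
#> [1] 0.6935484
```

Reading: the barrier/driving-force slope of 1.04 diagnoses late
transition states; the Ni–S bond-formation leg changes 2.8 kcal/mol per
kcal/mol of overall reaction free energy while the electron-transfer leg
counteracts at −1.8 (ratio ≈ 1.6), so the Ni–S bond strength, not the
reduction potential, dominates the reactivity trend; the polarization
slope 1.34 is recovered within 0.01 of the generator truth; and the
σ* orbital is 69% methyl-sided.

## Data formats

* **XYZ** (extended): trailing `F` token on an atom line marks a frozen
  atom.
* **Hessian**: header `natoms N units hartree_bohr2`, then the 3N×3N
  matrix, whitespace-separated, row-major.
* **Tables** (CSV/TSV): units declared as column-name suffixes
  (`E_el_hartree`, `G_kcal`, `q_Ni_e`, `NiS_dist_A`); energies are
  converted to kcal/mol on load and every numeric column carries a unit
  in `attr(x, "units")`.

A thin CLI over the same functions lives at `inst/cli/reactfactors`
(subcommands `ked`, `thermo`, `redox`, `cycle`, `polarize`, `correlate`,
`simulate`).
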