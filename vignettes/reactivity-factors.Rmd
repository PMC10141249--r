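---
title: "Reactivity factors of nickel corphinoid cofactor models: methods and design"
author: "reactfactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivity factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactfactors)
```

## The scientific problem

Methyl-coenzyme M reductase (MCR) produces methane in the final step of
methanogenesis. Its active site hosts the nickel corphinoid cofactor F430,
whose biosynthesis passes through a series of precursors with progressively
saturated macrocycles. Quantum-chemistry studies of cluster models of such
active sites ask *why* the mature cofactor is the best catalyst: which
electronic-structure factors — the Ni(II)/Ni(I) reduction potential, the
strength of the Ni–S bond formed during the rate-determining reductive
S–CH3 cleavage, the polarization response of the macrocyclic ligand, the
composition of the σ*(S–CH3) orbital — control the barrier, and how do they
trade off against each other across a model series?

`reactfactors` implements the *post-processing* layer of such a study. It
consumes what electronic-structure codes produce — geometries, Cartesian
Hessians, electronic energies, atomic-charge tables, orbital compositions,
bond descriptors — and computes the derived reactivity factors. It performs
no quantum chemistry itself: DFT energies, AIM charges and bond orders are
inputs, never outputs.

## Normal modes, frozen-atom projection and KED

Cluster models of enzyme active sites fix a few capping framework atoms at
crystallographic positions. Their degrees of freedom must not enter the
vibrational analysis: `project_frozen()` zeroes the frozen rows and columns
of the Cartesian Hessian (an orthogonal projection onto the unfrozen
subspace), and `normal_modes()` diagonalizes the mass-weighted matrix
`M^(-1/2) H M^(-1/2)`. With `f` frozen atoms of `n` the analysis yields
`3n − 3f` modes — for the 8-atom frozen framework convention, `3n − 24`
vibrations for minima and `3n − 25` real vibrations plus one imaginary mode
for transition states. Imaginary modes are stored as negative wavenumbers;
`is_ts()` flags a mode set with exactly one.

The kinetic energy distribution of a mode assigns each atom its fraction of
the mode's kinetic energy,

KED_iα = m_i |r_iα|² / Σ_k m_k |r_kα|²,

where `r_iα` is atom *i*'s Cartesian displacement 3-vector within mode α.
Each column of the KED matrix lies in [0, 1] and sums to 1, and the
statistic is invariant to the overall normalization of the displacement
vector (both are property-tested). `fragment_ked()` sums the statistic over
a fragment — for a transition state's reactive mode, the KED_CH3 of the
nascent methyl radical measures how ballistic the departing fragment is.
Per-atom kinetic energies can be aggregated over modes with user-supplied
per-mode energies via `atom_kinetic_energy()`; no thermal-population model
is imposed, because the reactive-mode analysis needs none.

Numerical choices:

* **Zero-mode threshold.** Modes with |ν̃| < 1 cm⁻¹ are treated as the
  numerical null space of the projector and dropped (configurable,
  `zero_tol`). Frozen-framework clusters have no rigid-body zero modes,
  so translation/rotation (Eckart) projection is available for free
  molecules (`project_trans_rot = TRUE`) but off by default.
* **Degeneracy.** Within a degenerate eigenvalue subspace the per-atom KED
  is not unique (eigenvector rotation freedom). Modes closer than
  0.01 cm⁻¹ are flagged and `fragment_ked()` warns on them.
* **Exact zeros.** After projection, eigenvector components on frozen
  coordinates are set to exactly zero (guarding against degenerate mixing
  in the null space) and the vectors renormalized.

## RRHO thermochemistry and redox potentials

`gibbs()` assembles `G = E_el + ZPVE + [pV − RT ln Q]` in the rigid-rotor /
harmonic-oscillator approximation at `T = 298 K`, `p = 1 bar` by default
(298.15 K selectable). The vibrational partition function is referenced to
the vibrational ground state, the ZPVE (`Σ hcν̃/2` over real modes) being
carried separately. Two regimes:

* **free-molecule** — translational (Sackur–Tetrode), rotational
  (classical rigid rotor, symmetry number `sigma`, default 1, with a
  linear-molecule special case detected from the inertia tensor) and
  vibrational terms, `pV = RT`.
* **frozen-cluster** — only the projected vibrational degrees of freedom
  contribute enthalpic and entropic terms. Whether a cluster species
  should also carry the ideal-gas `pV = RT` term is not a settled
  convention; both behaviours are provided (`include_pv`, default `TRUE`
  for consistency across regimes) and the term cancels in any balanced
  reaction anyway.

No quasi-harmonic damping of low frequencies is applied: the plain RRHO
value is the documented convention here, and the closed-form tests
(Sackur–Tetrode; harmonic-oscillator entropy) pin the implementation to
0.1%.

Reduction potentials follow the absolute-electrode convention:
`E° = (G_ox − G_red) − E°_abs(reference)` with energies in eV per particle
and the normal hydrogen electrode (4.28 eV) as default reference. The free
energy and solvation of the electron are absorbed in the reference. Pinned
conversions (`unit_constants`): 1 hartree = 627.5095 kcal/mol, 1 eV =
23.0605 kcal/mol, 1 cm⁻¹ = 2.85914e-3 kcal/mol, Coulomb constant 332.0637
kcal Å mol⁻¹ e⁻².

## Thermodynamic cycles and correlations

`build_step1_cycle()` dissects the reductive S–CH3 cleavage into homolysis
(`ΔG′_cleavage`), Ni(I)→thiyl electron transfer (`ΔG′_ET`) and
Ni(II)–thiolate bond formation (`ΔG′_NiS`), from free energies of isolated
species; `build_step3_cycle()` does the same for the S–S coupling step
(Ni–S cleavage, thiolate→Ni(II) electron transfer, disulfide formation).
Seven corner species are required for step 1 — the isolated Ni(II) complex
appears in two legs and cancels in the total — and the constructors verify
closure against the direct state-function value to 1e-9 kcal/mol. The
charge and protonation identity of each corner is deliberately left to the
caller's ledger; the cycle algebra does not depend on it. The ET corners
default to singlet Ni(II) species; since only `G` values enter, the
triplet-corner variant is expressed by supplying that ledger.

`bep_regression()` fits ΔG‡ against ΔG₀ across a model series (unweighted
OLS; a slope near 1 diagnoses late transition states).
`leg_correlations()` regresses each step-1 leg on the overall ΔG′₀,₁; the
ratio of the Ni–S slope to the magnitude of the ET slope measures which
factor dominates the reactivity trend. When potentials are supplied, E° (V)
is regressed on the total converted to eV, which by
`ΔG′_ET = F(E°_Ni − E°_ref couple)` coincides with the ET-leg slope.

## Ligand polarization

The electron-donation responsiveness of a macrocycle is probed by replacing
the central metal with a point charge `q_P` and recording atomic charges on
a grid (0 → 1 e in 0.1 e steps by default). The polarization statistic is
the summed absolute charge shift

P(q_P) = Σ_i |q_i(q_P) − q_i(0)|,

chosen as the simplest form consistent with linear printed curves and
slopes of order one per unit probe charge; a sum-of-squares variant is
available (`squared = TRUE`), and the atom subset over which the sum runs
is configurable (`atoms`), so a ligand-only summation excluding any probe
site is a one-argument change. `P(0) = 0` identically, so the default
slope fit constrains the intercept to zero; the free-intercept fit is
always reported alongside as a diagnostic. On noisy data the fixed-zero
estimator carries a small positive bias (absolute values fold noise on
near-zero shifts upward); at the default noise level (sd 0.005 e, 25
atoms, 11-point grid) this measures about +0.01 e/e, under 1% of the
slopes of interest, which is why no bias correction is applied.

## Scalar descriptors

`f_ch3()` computes `F_CH3 = p_C/(p_C + p_S)`, the carbon share of the
σ*(S–CH3) orbital; `coulomb_differential()` gives the point-charge estimate
of the differential Ni–ligand electrostatic interaction between two models
(per-bond charges over the mean Ni–N distance, times the number of
equivalent bonds — purely electrostatic, covalency excluded; no dielectric
screening is applied, matching the bare-Coulomb convention of the
estimate); `trend_fit()` performs the cross-model OLS/Pearson fits (Ni–N vs
Ni–S distances, delocalization indices, bond orders, KED_CH3 vs F_CH3). All
bond orders, delocalization indices and AIM charges are consumed as
tabulated inputs.

## What the synthetic generators emulate

The package must be testable without electronic-structure software, so
`gen_*` functions produce every input with the structural properties the
analysis assumes. They emulate the *statistics* of quantum-chemistry
outputs, not their physics:

* `gen_coupled_oscillator()` — linear-chain Hessians with closed-form
  longitudinal spectra (the three-atom uniform chain's 1 : √3 ratio is the
  oracle); `gen_random_hessian()` — dense random symmetric matrices for
  stress tests.
* `gen_ts_mode()` — a reactive mode whose fragment KED equals a prescribed
  share *exactly* (the mass-weighted displacement is solved from the KED
  definition), plus random orthogonal real modes.
* `gen_charge_response()` — linear per-atom responses with Σ|a_i| equal to
  the truth slope plus Gaussian charge noise; presets A–E carry slopes
  1.34 … 1.02. Only the end members mirror printed values; B–D are linear
  interpolations, labelled synthetic.
* `gen_model_series()` — a five-model free-energy series whose cycles
  close exactly on constructed legs: the cleavage leg constant, Ni–S and
  ET legs linear in the overall ΔG′₀,₁ with slopes 2.8 and −1.8, late
  transition states (G_TS − G_Int uniform in [2, 5] kcal/mol, so ΔG‡
  tracks ΔG₀ with slope ≈ 1), overall step-1 free energies
  (22, 26, 12, 8, 3) kcal/mol for A–E giving the barrier ordering
  E < D < C < A < B, potentials increasing along B < A < C < D < E
  (anchored by a thiyl/thiolate reference couple at 0.75 V), and a
  step-3 S–S leg of −80 kcal/mol keeping that step exergonic throughout
  and least exergonic for the last model. Absolute corner free energies
  (e.g. a ~79 kcal/mol homolysis leg) are placed in chemically sensible
  ranges but are constructions, not computed data.

What passing tests on these fixtures shows: the estimators recover known
truths under the assumed data model (linearity, Gaussian charge noise,
exact cycle closure, harmonic force fields). What they cannot show:
behaviour under anharmonicity, non-linear charge responses, correlated
noise, or basis-set/functional error in the consumed energies — all of
which live upstream of this package.

## Problem sizes and determinism

All fixtures are small by design — chains of 2–8 atoms, random clusters of
up to 12 atoms, 5-model series, 11-point charge grids, a few hundred
random ledgers — so the whole suite runs in seconds while still exercising
every code path, including 100-seed property sweeps. Every generator takes
an explicit seed and is bit-reproducible; test and script seeds are fixed
in the code.

## A worked example

```{r example}
series <- gen_model_series(series_spec(), seed = 42)
bep_regression(series$energetics)[c("slope", "r")]

led <- as.data.frame(series$ledger)
cycles <- lapply(series$legs$model, function(m)
  build_step1_cycle(fe_ledger(led[led$model == m, ])))
leg_correlations(cycles, series$potentials$E0)

crA <- gen_charge_response(25, preset = "A", noise_sd = 0.005, seed = 7)
polarization_slope(polarization_curve(crA))$m

f_ch3(p_C = 43, p_S = 19)
```

## Known limitations

* Plain RRHO only: no quasi-harmonic entropy damping, no anharmonicity,
  no hindered-rotor treatment.
* The Eckart projector assumes a reasonable reference geometry; gradient
  (non-stationary-point) corrections to the projection are not applied.
* The polarization statistic's absolute-value form is one of several
  defensible readings of "summed charge response"; the squared variant is
  provided, but e.g. dipole-resolved polarization is not.
* Native quantum-chemistry log files are not parsed; inputs arrive in the
  documented plain-text formats (XYZ with frozen flags, headered Hessian
  text, delimited tables with unit-suffixed columns).
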