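Package: reactfactors
Title: Reactivity Factor Analysis for Nickel Corphinoid Cofactor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for quantum-chemistry studies of
    methyl-coenzyme M reductase (MCR), its F430 cofactor and the cofactor's
    biosynthetic precursors. Implements mass-weighted normal-mode analysis
    with frozen-atom projection for cluster models, the kinetic energy
    distribution (KED) statistic of reactive transition-state modes,
    rigid-rotor/harmonic-oscillator Gibbs free-energy assembly, reduction
    potentials against an absolute electrode reference, thermodynamic-cycle
    decomposition of the reductive S-CH3 cleavage and S-S coupling steps,
    ligand-polarization probing from atomic-charge response tables, scalar
    orbital and bonding descriptors, linear free-energy (BEP-type) and
    cross-model correlations, and seeded synthetic-data generators that
    emulate the quantum-chemistry outputs so the whole pipeline is testable
    without electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
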