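#' Physical constants and unit conversions
#'
#' Pinned conversion factors used throughout the package. Energies are kept
#' internally in kcal/mol, potentials in V, charges in e, distances in
#' Angstrom, wavenumbers in cm^-1.
#'
#' @format Named numeric vector with elements:
#' \describe{
#'   \item{hartree_kcal}{1 hartree in kcal/mol (627.5095)}
#'   \item{ev_kcal}{1 eV in kcal/mol (23.0605)}
#'   \item{cm1_kcal}{1 cm^-1 in kcal/mol (2.85914e-3)}
#'   \item{coulomb_kcal}{Coulomb constant, kcal A mol^-1 e^-2 (332.0637)}
#'   \item{R_kcal}{gas constant, kcal mol^-1 K^-1}
#'   \item{R_J}{gas constant, J mol^-1 K^-1}
#'   \item{nhe_abs_ev}{absolute potential of the normal hydrogen electrode, eV}
#' }
#' @export
unit_constants <- c(
  hartree_kcal = 627.5095,
  ev_kcal      = 23.0605,
  cm1_kcal     = 2.85914e-3,
  coulomb_kcal = 332.0637,
  R_kcal       = 1.987204259e-3,
  R_J          = 8.314462618,
  nhe_abs_ev   = 4.28
)

# SI constants used only for frequency / partition-function conversions
.const <- list(
  h_J      = 6.62607015e-34,    # Planck, J s
  kB_J     = 1.380649e-23,      # Boltzmann, J/K
  c_cm     = 2.99792458e10,     # speed of light, cm/s
  NA_mol   = 6.02214076e23,
  amu_kg   = 1.66053906660e-27,
  Eh_J     = 4.3597447222071e-18,
  bohr_m   = 5.29177210903e-11
)

# sqrt(eigenvalue [hartree bohr^-2 amu^-1]) -> wavenumber in cm^-1
.freq_factor <- local({
  with(.const, sqrt(Eh_J / (bohr_m^2 * amu_kg)) / (2 * pi * c_cm))
})

# hc/kB in K cm: vibrational temperature Theta_v = .theta_cm * nu_tilde
.theta_cm <- local(with(.const, h_J * c_cm / kB_J))
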