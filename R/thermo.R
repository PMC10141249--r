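#' Zero-point vibrational energy
#'
#' `ZPVE = sum_k h c nu_k / 2` over real modes; imaginary (negative)
#' frequencies contribute nothing.
#'
#' @param modes a [mode_set()], or a numeric vector of wavenumbers (cm^-1).
#' @return energy in kcal/mol.
#' @export
zpve <- function(modes) {
  freq <- if (inherits(modes, "mode_set")) modes$freq else modes
  freq <- freq[freq > 0]
  if (!length(freq)) return(0)
  sum(freq) * unit_constants[["cm1_kcal"]] / 2
}

# per-mode harmonic-oscillator thermal functions (ZPVE excluded)
# returns list(E = thermal energy kcal/mol, S = entropy kcal/mol/K)
.vib_thermal <- function(freq, T) {
  freq <- freq[freq > 0]
  R <- unit_constants[["R_kcal"]]
  if (!length(freq)) return(list(E = 0, S = 0))
  theta <- .theta_cm * freq          # vibrational temperatures, K
  x <- theta / T
  E <- R * sum(theta / (exp(x) - 1))
  S <- R * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  list(E = E, S = S)
}

# Sackur-Tetrode style translational functions at pressure p (bar)
.trans_thermal <- function(mass_amu, T, p) {
  R <- unit_constants[["R_kcal"]]
  m <- sum(mass_amu) * .const$amu_kg
  V <- .const$kB_J * T / (p * 1e5)                 # volume per molecule, m^3
  q <- (2 * pi * m * .const$kB_J * T / .const$h_J^2)^1.5 * V
  list(E = 1.5 * R * T, S = R * (log(q) + 2.5))
}

# rigid-rotor rotational functions from the inertia tensor
.rot_thermal <- function(structure, T, sigma = 1) {
  R <- unit_constants[["R_kcal"]]
  m <- structure$masses
  if (length(m) == 1L) return(list(E = 0, S = 0, linear = NA))
  com <- colSums(structure$coords * m) / sum(m)
  x <- sweep(structure$coords, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_along(m)) {
    r <- x[i, ]
    I <- I + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values) # amu A^2
  mom_SI <- mom * .const$amu_kg * 1e-20
  hbar <- .const$h_J / (2 * pi)
  linear <- mom_SI[1] < 1e-3 * mom_SI[3]
  if (linear) {
    theta <- hbar^2 / (2 * mom_SI[3] * .const$kB_J)
    q <- T / (sigma * theta)
    list(E = R * T, S = R * (log(q) + 1), linear = TRUE)
  } else {
    theta <- hbar^2 / (2 * mom_SI * .const$kB_J)
    q <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
    list(E = 1.5 * R * T, S = R * (log(q) + 1.5), linear = FALSE)
  }
}

#' Thermal correction to the Gibbs free energy (beyond ZPVE)
#'
#' The `pV - RT ln Q` term of the RRHO Gibbs assembly, with the vibrational
#' partition function referenced to the vibrational ground state (the ZPVE
#' is carried separately by [zpve()]). Two regimes:
#' \describe{
#'   \item{`free-molecule`}{translational + rotational + vibrational
#'     partition functions, ideal-gas `pV = RT`.}
#'   \item{`frozen-cluster`}{vibrational contributions only -- exactly the
#'     projected degrees of freedom enter the enthalpic and entropic terms.
#'     The `pV = RT` term is retained by default for consistency across
#'     regimes; set `include_pv = FALSE` to drop it.}
#' }
#'
#' @param modes a [mode_set()] (imaginary modes are excluded), or numeric
#'   wavenumbers.
#' @param structure the [xyz_structure()] (needed for masses/geometry in the
#'   free-molecule regime; optional for frozen clusters).
#' @param T temperature in K (default 298).
#' @param p pressure in bar (default 1).
#' @param regime `"frozen-cluster"` or `"free-molecule"`.
#' @param sigma rotational symmetry number (free-molecule regime).
#' @param include_pv retain the `pV = RT` term (default `TRUE`).
#' @return energy in kcal/mol, with attribute `"components"` (named list of
#'   thermal energies and entropies, kcal/mol and kcal/mol/K).
#' @export
thermal_correction <- function(modes, structure = NULL, T = 298, p = 1,
                               regime = c("frozen-cluster", "free-molecule"),
                               sigma = 1, include_pv = TRUE) {
  regime <- match.arg(regime)
  if (T <= 0) stop("T must be positive")
  freq <- if (inherits(modes, "mode_set")) modes$freq else modes
  R <- unit_constants[["R_kcal"]]
  vib <- .vib_thermal(freq, T)
  if (regime == "free-molecule") {
    if (is.null(structure))
      stop("free-molecule regime needs the structure (masses and geometry)")
    tr <- .trans_thermal(structure$masses, T, p)
    rot <- .rot_thermal(structure, T, sigma)
  } else {
    tr <- list(E = 0, S = 0)
    rot <- list(E = 0, S = 0)
  }
  pv <- if (include_pv) R * T else 0
  E_therm <- vib$E + tr$E + rot$E
  S_tot <- vib$S + tr$S + rot$S
  out <- E_therm + pv - T * S_tot
  attr(out, "components") <- list(
    E_vib = vib$E, E_trans = tr$E, E_rot = rot$E,
    S_vib = vib$S, S_trans = tr$S, S_rot = rot$S, pV = pv, T = T, p = p,
    regime = regime)
  out
}

#' Assemble a Gibbs free energy (RRHO)
#'
#' `G = E_el + ZPVE + [pV - RT ln Q]`: electronic energy plus zero-point
#' vibrational energy plus the thermal enthalpic/entropic correction of
#' [thermal_correction()].
#'
#' @param E_el electronic energy, kcal/mol.
#' @param modes a [mode_set()] (may be `NULL` for no vibrational DOF).
#' @param structure the [xyz_structure()] (free-molecule regime).
#' @param species species label.
#' @inheritParams thermal_correction
#' @return a one-row `fe_ledger` data.frame with columns `species`, `E_el`,
#'   `zpve`, `thermal`, `G`, `T`, `p`, `regime` (energies kcal/mol).
#' @export
gibbs <- function(E_el, modes = NULL, structure = NULL, T = 298, p = 1,
                  regime = c("frozen-cluster", "free-molecule"),
                  species = "", sigma = 1, include_pv = TRUE) {
  regime <- match.arg(regime)
  z <- if (is.null(modes)) 0 else zpve(modes)
  th <- as.numeric(thermal_correction(
    if (is.null(modes)) numeric(0) else modes, structure,
    T = T, p = p, regime = regime, sigma = sigma, include_pv = include_pv))
  fe_ledger(data.frame(species = species, E_el = E_el, zpve = z,
                       thermal = th, G = E_el + z + th, T = T, p = p,
                       regime = regime, stringsAsFactors = FALSE))
}

#' Free-energy ledger
#'
#' Per-species table of Gibbs free-energy components (kcal/mol). The
#' constructor validates the assembly identity
#' `G = E_el + zpve + thermal` to 1e-9 kcal/mol on every row.
#'
#' @param df data.frame with columns `species`, `E_el`, `zpve`, `thermal`,
#'   `G` (kcal/mol) and optionally `T`, `p`, `regime`, `model`. Missing
#'   `zpve`/`thermal` default to 0; missing `G` is assembled.
#' @return data.frame of class `fe_ledger`.
#' @export
fe_ledger <- function(df) {
  df <- as.data.frame(df)
  if (!"species" %in% names(df)) stop("ledger needs a 'species' column")
  if (!"E_el" %in% names(df)) stop("ledger needs an 'E_el' column")
  if (!"zpve" %in% names(df)) df$zpve <- 0
  if (!"thermal" %in% names(df)) df$thermal <- 0
  if (!"G" %in% names(df)) df$G <- df$E_el + df$zpve + df$thermal
  if (!"T" %in% names(df)) df$T <- 298
  if (any(df$T <= 0)) stop("T must be positive")
  resid <- abs(df$G - df$E_el - df$zpve - df$thermal)
  if (any(resid > 1e-9))
    stop("ledger identity G = E_el + zpve + thermal violated by up to ",
         format(max(resid)), " kcal/mol")
  class(df) <- c("fe_ledger", "data.frame")
  df
}

#' Reduction potential from a redox couple
#'
#' `E0 = (G_ox - G_red) - E_abs_reference`, with the free energies of the
#' oxidized and reduced species in eV per particle (the Faraday constant
#' cancels on this scale) and the reference the absolute potential of the
#' reference electrode -- by default the normal hydrogen electrode,
#' 4.28 eV. The free energy and solvation of the electron are absorbed in
#' the reference, the standard absolute-potential convention.
#'
#' @param G_ox,G_red Gibbs free energies of the oxidized and reduced forms,
#'   eV.
#' @param reference absolute reference-electrode potential, eV
#'   (default 4.28, NHE).
#' @return potential in V (vs the reference electrode).
#' @export
redox_potential <- function(G_ox, G_red,
                            reference = unit_constants[["nhe_abs_ev"]]) {
  if (reference <= 0) stop("reference potential must be positive")
  (G_ox - G_red) - reference
}
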