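#' Carbon fraction of the S-CH3 sigma* orbital
#'
#' `F_CH3 = p_C / (p_C + p_S)`: the fraction of the carbon p contribution
#' in the sigma*(S-CH3) orbital relative to sulfur. A larger F_CH3 means
#' the antibonding orbital is polarized toward the methyl group, which
#' correlates with the kinetic-energy concentration on the nascent methyl
#' radical in the reactive mode (KED_CH3).
#'
#' @param p_C,p_S percent contributions of the carbon and sulfur p atomic
#'   orbitals (each in [0, 100]; they need not sum to 100).
#' @return fraction in [0, 1].
#' @export
f_ch3 <- function(p_C, p_S) {
  if (any(p_C < 0) || any(p_S < 0) || any(p_C > 100) || any(p_S > 100))
    stop("percent contributions must lie in [0, 100]")
  if (any(p_C + p_S == 0)) stop("p_C + p_S must be positive")
  p_C / (p_C + p_S)
}

#' Differential Coulombic metal-ligand interaction
#'
#' Point-charge estimate of how much weaker (or stronger) the Ni-N
#' electrostatic interaction is in model A than in model B:
#' `n_bonds * 332.0637 * (qNi_A qN_A / r_A - qNi_B qN_B / r_B)` kcal/mol,
#' using AIM charges (e) and the mean Ni-N distance (Angstrom). Purely
#' electrostatic: the covalent component of bonding is outside this
#' estimate.
#'
#' @param rowA,rowB lists or one-row data.frames with fields `q_Ni`, `q_N`
#'   (e) and `NiN_dist` (Angstrom).
#' @param n_bonds number of equivalent Ni-N bonds (default 4).
#' @return energy difference in kcal/mol (A minus B); antisymmetric in its
#'   two arguments.
#' @export
coulomb_differential <- function(rowA, rowB, n_bonds = 4) {
  term <- function(r) {
    if (r$NiN_dist <= 0) stop("distances must be positive")
    r$q_Ni * r$q_N / r$NiN_dist
  }
  n_bonds * unit_constants[["coulomb_kcal"]] * (term(rowA) - term(rowB))
}

#' Linear trend fit with Pearson correlation
#'
#' OLS fit of `y` on `x` plus the Pearson correlation coefficient. Used
#' for the cross-model descriptor trends: mean Ni-N vs Ni-S bond length
#' (expected negative slope), delocalization-index and bond-order
#' correlations, and KED_CH3 vs F_CH3.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return list with `slope`, `intercept`, `r`, `n`.
#' @export
trend_fit <- function(x, y) .ols(x, y)
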