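# Canonical species labels for the two thermodynamic cycles.
# step 1 (reductive S-CH3 cleavage):
#   ch3scom     H3C-SCoM thioether substrate
#   ch3_rad     CH3 radical
#   scom_rad    thiyl radical of coenzyme M
#   scom_anion  thiolate anion of coenzyme M (post electron transfer)
#   ni1         isolated Ni(I) macrocyclic complex
#   ni2         isolated Ni(II) complex (cancels in the total)
#   ni2_scom    Ni(II)-thiolate complex
# step 3 additionally:
#   cobs_rad    thiyl radical of coenzyme B
#   ss_adduct   S-S coupled CoBS-SCoM product
.step1_species <- c("ch3scom", "ch3_rad", "scom_rad", "scom_anion",
                    "ni1", "ni2", "ni2_scom")
.step3_species <- c("ni2_scom", "ni2", "scom_anion", "scom_rad", "ni1",
                    "cobs_rad", "ss_adduct")

.ledger_G <- function(ledger, species, step) {
  i <- match(species, ledger$species)
  if (is.na(i))
    stop("ledger is missing the '", species, "' corner species of the ",
         step, " cycle")
  ledger$G[i]
}

#' Construct a thermodynamic cycle object
#'
#' @param step `"step1"` or `"step3"`.
#' @param legs named numeric vector of leg free energies (kcal/mol):
#'   step 1 uses `cleavage`, `ET`, `NiS`; step 3 uses `NiS_cleavage`, `ET`,
#'   `S_S`.
#' @param direct optional independently computed overall free energy
#'   (kcal/mol); the closure `sum(legs) == direct` is checked to 1e-9.
#' @return object of class `thermo_cycle` with fields `step`, `legs`,
#'   `total`, `direct`.
#' @export
thermo_cycle <- function(step = c("step1", "step3"), legs, direct = NULL) {
  step <- match.arg(step)
  want <- if (step == "step1") c("cleavage", "ET", "NiS")
          else c("NiS_cleavage", "ET", "S_S")
  if (!setequal(names(legs), want))
    stop(step, " cycle needs legs: ", paste(want, collapse = ", "))
  legs <- legs[want]
  total <- sum(legs)
  if (!is.null(direct) && abs(total - direct) > 1e-9)
    stop("cycle closure violated: sum of legs ", format(total),
         " differs from direct value ", format(direct))
  structure(list(step = step, legs = legs, total = total, direct = direct),
            class = "thermo_cycle")
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat(sprintf("<thermo_cycle> %s: total %.3f kcal/mol\n", x$step, x$total))
  for (nm in names(x$legs))
    cat(sprintf("  dG'_%-12s %10.3f\n", nm, x$legs[[nm]]))
  invisible(x)
}

#' Decompose catalytic step 1 into a thermodynamic cycle
#'
#' The rate-determining reductive S-CH3 cleavage is dissected into three
#' legs built from free energies of isolated species:
#' homolytic cleavage `dG'_cleavage = G(ch3_rad) + G(scom_rad) -
#' G(ch3scom)`; electron transfer from Ni(I) to the thiyl radical
#' `dG'_ET = G(ni2) + G(scom_anion) - G(ni1) - G(scom_rad)`; Ni(II)-thiolate
#' bond formation `dG'_NiS = G(ni2_scom) - G(ni2) - G(scom_anion)`. Their
#' sum is the overall `dG'_0,1` (the isolated Ni(II) complex cancels).
#'
#' @param ledger an [fe_ledger()] containing the seven corner species
#'   (labels `ch3scom`, `ch3_rad`, `scom_rad`, `scom_anion`, `ni1`, `ni2`,
#'   `ni2_scom`).
#' @return a [thermo_cycle()] with `direct` set to the state-function value
#'   `G(ch3_rad) + G(ni2_scom) - G(ni1) - G(ch3scom)`.
#' @export
build_step1_cycle <- function(ledger) {
  g <- function(s) .ledger_G(ledger, s, "step1")
  legs <- c(
    cleavage = g("ch3_rad") + g("scom_rad") - g("ch3scom"),
    ET       = g("ni2") + g("scom_anion") - g("ni1") - g("scom_rad"),
    NiS      = g("ni2_scom") - g("ni2") - g("scom_anion"))
  direct <- g("ch3_rad") + g("ni2_scom") - g("ni1") - g("ch3scom")
  thermo_cycle("step1", legs, direct)
}

#' Decompose catalytic step 3 into a thermodynamic cycle
#'
#' The S-S coupling step, from the cofactor's perspective the reverse of
#' step 1: Ni-S cleavage `dG'_NiS_cleavage = G(ni2) + G(scom_anion) -
#' G(ni2_scom)`; thiolate-to-Ni(II) electron transfer `dG'_ET = G(ni1) +
#' G(scom_rad) - G(ni2) - G(scom_anion)`; disulfide bond formation
#' `dG'_S_S = G(ss_adduct) - G(scom_rad) - G(cobs_rad)`.
#'
#' @param ledger an [fe_ledger()] with the step-3 corner species.
#' @return a [thermo_cycle()] with `direct` the state-function total.
#' @export
build_step3_cycle <- function(ledger) {
  g <- function(s) .ledger_G(ledger, s, "step3")
  legs <- c(
    NiS_cleavage = g("ni2") + g("scom_anion") - g("ni2_scom"),
    ET           = g("ni1") + g("scom_rad") - g("ni2") - g("scom_anion"),
    S_S          = g("ss_adduct") - g("scom_rad") - g("cobs_rad"))
  direct <- g("ni1") + g("ss_adduct") - g("ni2_scom") - g("cobs_rad")
  thermo_cycle("step3", legs, direct)
}

#' Activation / reaction free-energy (BEP-type) regression
#'
#' Ordinary least squares of the activation free energy on the reaction
#' free energy across a model series. A slope near 1 is the signature of a
#' late transition state: the barrier tracks the thermodynamics.
#'
#' @param energetics data.frame with columns `dG_act` and `dG0` (kcal/mol),
#'   one row per model (>= 3 rows).
#' @return list with `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
bep_regression <- function(energetics) {
  x <- energetics$dG0
  y <- energetics$dG_act
  .ols(x, y)
}

.ols <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 models")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0) stop("zero variance in the x variable")
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, n = length(x))
}

#' Leg-vs-total correlations across a cycle series
#'
#' Across a series of step-1 cycles, regresses each cycle leg on the
#' overall `dG'_0,1`. The Ni-S leg slope against the electron-transfer leg
#' slope quantifies which factor dominates the trend in reactivity (the
#' slope ratio). When reduction potentials are supplied, the slope of `E0`
#' (V) against the total converted to eV is reported as well; by
#' `dG'_ET = F (E0_Ni - E0_ref_couple)` it coincides with the ET-leg slope
#' up to the sign convention of the potential scale.
#'
#' @param cycles list of step-1 [thermo_cycle()] objects (>= 3), one per
#'   model.
#' @param potentials optional numeric vector of reduction potentials (V),
#'   one per cycle.
#' @return data.frame with one row per quantity (`NiS`, `ET`, `cleavage`,
#'   and `E0` when given): columns `quantity`, `slope`, `intercept`, `r`;
#'   attribute `"slope_ratio"` = slope(NiS)/|slope(ET)|.
#' @export
leg_correlations <- function(cycles, potentials = NULL) {
  if (length(cycles) < 3) stop("need at least 3 models")
  if (!all(vapply(cycles, function(cc) cc$step == "step1", logical(1))))
    stop("leg correlations are defined for step-1 cycles")
  tot <- vapply(cycles, function(cc) cc$total, numeric(1))
  rows <- lapply(c("NiS", "ET", "cleavage"), function(nm) {
    y <- vapply(cycles, function(cc) cc$legs[[nm]], numeric(1))
    f <- .ols(tot, y)
    data.frame(quantity = nm, slope = f$slope, intercept = f$intercept,
               r = f$r, stringsAsFactors = FALSE)
  })
  if (!is.null(potentials)) {
    if (length(potentials) != length(cycles))
      stop("one potential per cycle required")
    f <- .ols(tot / unit_constants[["ev_kcal"]], potentials)
    rows <- c(rows, list(data.frame(quantity = "E0", slope = f$slope,
                                    intercept = f$intercept, r = f$r,
                                    stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  et <- out$slope[out$quantity == "ET"]
  attr(out, "slope_ratio") <- out$slope[out$quantity == "NiS"] / abs(et)
  out
}
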