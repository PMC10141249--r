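#' Construct a charge-response object
#'
#' Atomic charges `q_i(q_P)` of a macrocyclic ligand probed by a central
#' point charge `q_P` placed at the metal site, on a grid of probe values.
#'
#' @param charges n_atoms x n_grid numeric matrix of atomic charges (e).
#' @param grid numeric vector of probe charges (e); strictly increasing and
#'   starting at 0.
#' @param label model label.
#' @return object of class `charge_response`.
#' @export
charge_response <- function(charges, grid, label = "") {
  charges <- as.matrix(charges)
  if (ncol(charges) != length(grid))
    stop("one charge column per probe grid point required")
  if (!all(is.finite(charges))) stop("charges must be finite")
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("probe grid must be strictly increasing")
  if (grid[1] != 0) stop("probe grid must start at q_P = 0")
  structure(list(charges = charges, grid = grid, label = label),
            class = "charge_response")
}

#' @export
print.charge_response <- function(x, ...) {
  cat(sprintf("<charge_response> %d atoms, probe grid %g..%g e (%d points)%s\n",
              nrow(x$charges), min(x$grid), max(x$grid), length(x$grid),
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Convert a `charges`-schema table to a charge_response
#'
#' @param tab a `react_table` from [read_table()] with the `charges` schema;
#'   probe columns named like `q_0.0`, `q_0.1`, ...
#' @param label model label.
#' @return a [charge_response()].
#' @export
as_charge_response <- function(tab, label = "") {
  probe <- grep("^q_?P?_?[0-9.]+$|^(qP|q)[._][0-9.]+$", names(tab),
                value = TRUE)
  grid <- as.numeric(sub("^q_?P?[._]?", "", probe))
  ord <- order(grid)
  charge_response(as.matrix(as.data.frame(tab)[, probe[ord]]), grid[ord],
                  label = label)
}

#' Ligand polarization curve
#'
#' `P(q_P) = sum_i |q_i(q_P) - q_i(0)|`: the total absolute atomic-charge
#' shift of the ligand in response to the central probe charge. `P(0) = 0`
#' by construction. A sum-of-squares variant is available behind
#' `squared = TRUE`.
#'
#' @param response a [charge_response()].
#' @param atoms optional integer subset of atoms over which the sum runs
#'   (default: all atoms).
#' @param squared use squared deviations instead of absolute values.
#' @return data.frame with columns `q_P` (e) and `P` (e).
#' @export
polarization_curve <- function(response, atoms = NULL, squared = FALSE) {
  i0 <- which(response$grid == 0)
  if (!length(i0)) stop("probe grid does not include q_P = 0")
  q <- response$charges
  if (!is.null(atoms)) q <- q[atoms, , drop = FALSE]
  dq <- sweep(q, 1, q[, i0[1]])
  P <- if (squared) colSums(dq^2) else colSums(abs(dq))
  data.frame(q_P = response$grid, P = unname(P))
}

#' Polarization slope
#'
#' OLS slope of `P(q_P)` against `q_P`. Since `P(0) = 0` by definition, the
#' default fit constrains the intercept to zero; the free-intercept fit is
#' reported alongside as a diagnostic.
#'
#' @param curve data.frame from [polarization_curve()] (columns `q_P`, `P`),
#'   or a [charge_response()] (curve computed on the fly).
#' @param intercept_mode `"fixed-zero"` (default) or `"free"`; selects which
#'   slope is returned as `m`.
#' @return list with `m` (e per e of probe charge), `intercept_mode`,
#'   `m_fixed`, `m_free`, `intercept_free`, `r_squared`, `max_residual`, `n`.
#' @export
polarization_slope <- function(curve, intercept_mode = c("fixed-zero",
                                                         "free")) {
  intercept_mode <- match.arg(intercept_mode)
  if (inherits(curve, "charge_response")) curve <- polarization_curve(curve)
  x <- curve$q_P
  y <- curve$P
  if (length(x) < 3) stop("need at least 3 grid points")
  m_fixed <- sum(x * y) / sum(x^2)
  fit <- stats::lm(y ~ x)
  m_free <- unname(stats::coef(fit)[2])
  b_free <- unname(stats::coef(fit)[1])
  resid_fixed <- y - m_fixed * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid_fixed^2) / ss_tot else 1
  list(m = if (intercept_mode == "fixed-zero") m_fixed else m_free,
       intercept_mode = intercept_mode, m_fixed = m_fixed, m_free = m_free,
       intercept_free = b_free, r_squared = r2,
       max_residual = max(abs(resid_fixed)), n = length(x))
}
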