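#' Construct a normal-mode set
#'
#' Holds vibrational frequencies (cm^-1, imaginary modes stored as negative
#' values), Cartesian displacement vectors, and the per-atom kinetic energy
#' distribution (KED) matrix, filled by [compute_ked()].
#'
#' @param freq numeric vector of wavenumbers (cm^-1); imaginary modes
#'   negative.
#' @param displacements 3n x n_modes matrix of Cartesian displacements,
#'   atom-major (x1, y1, z1, x2, ...).
#' @param structure the matching [xyz_structure()].
#' @param degenerate_tol frequencies closer than this (cm^-1) are flagged as
#'   degenerate pairs (eigenvector rotation freedom makes per-atom KED
#'   non-unique within the subspace).
#' @return object of class `mode_set` with fields `freq`, `displacements`,
#'   `ked`, `degenerate`, `structure`, `dof_counts`.
#' @export
mode_set <- function(freq, displacements, structure, degenerate_tol = 0.01) {
  displacements <- as.matrix(displacements)
  n <- length(structure$elements)
  stopifnot(nrow(displacements) == 3L * n,
            ncol(displacements) == length(freq))
  ord <- order(freq)
  freq <- freq[ord]
  displacements <- displacements[, ord, drop = FALSE]
  degenerate <- rep(FALSE, length(freq))
  if (length(freq) > 1) {
    close_pairs <- abs(diff(freq)) < degenerate_tol
    degenerate[which(close_pairs)] <- TRUE
    degenerate[which(close_pairs) + 1L] <- TRUE
  }
  obj <- structure(
    list(freq = freq, displacements = displacements, ked = NULL,
         degenerate = degenerate, structure = structure,
         dof_counts = c(dof_counts(structure),
                        n_modes = length(freq))),
    class = "mode_set")
  compute_ked(obj)
}

#' @export
print.mode_set <- function(x, ...) {
  n_imag <- sum(x$freq < 0)
  cat(sprintf("<mode_set> %d modes (%d imaginary), n = %d atoms, f = %d frozen\n",
              length(x$freq), n_imag, x$dof_counts[["n"]],
              x$dof_counts[["f"]]))
  if (length(x$freq))
    cat("  frequencies (cm^-1):", paste(sprintf("%.1f", utils::head(x$freq, 8)),
                                        collapse = ", "),
        if (length(x$freq) > 8) "..." else "", "\n")
  invisible(x)
}

#' Is a mode set a transition-state mode set?
#'
#' @param modes a [mode_set()].
#' @return `TRUE` when exactly one imaginary (negative) frequency is present.
#' @export
is_ts <- function(modes) sum(modes$freq < 0) == 1L

#' Mass-weighted normal-mode analysis
#'
#' Diagonalizes the mass-weighted Hessian M^{-1/2} H M^{-1/2}; eigenvalues
#' are converted to wavenumbers (negative eigenvalues to negative "imaginary"
#' frequencies), eigenvectors un-mass-weighted to Cartesian displacements.
#' Null-space modes (|nu| < `zero_tol` cm^-1) -- the projected frozen-atom
#' coordinates and, when requested, overall translation/rotation -- are
#' dropped. Modes are sorted ascending by frequency.
#'
#' @param hessian a [cart_hessian()] in hartree/bohr^2, already passed
#'   through [project_frozen()] when the structure has frozen atoms.
#' @param structure the matching [xyz_structure()].
#' @param project_trans_rot project out rigid translations and rotations
#'   (Eckart projection) before diagonalizing. Intended for free molecules;
#'   leave `FALSE` for frozen-framework clusters, whose fixed atoms already
#'   remove global motion.
#' @param zero_tol wavenumber threshold (cm^-1) below which a mode is
#'   treated as numerical null space and dropped.
#' @param expect_ts if `TRUE`, error unless exactly one imaginary frequency
#'   survives (the 3n - 3f - 1 transition-state convention).
#' @return a [mode_set()] with the KED matrix filled.
#' @export
normal_modes <- function(hessian, structure, project_trans_rot = FALSE,
                         zero_tol = 1, expect_ts = FALSE) {
  n <- length(structure$elements)
  if (nrow(hessian) != 3L * n)
    stop("Hessian dimension does not match structure")
  if (any(structure$frozen)) {
    idx <- which(rep(structure$frozen, each = 3L))
    if (max(abs(as.matrix(hessian)[idx, ])) > 0)
      stop("structure has frozen atoms but the Hessian is not ",
           "frozen-projected; call project_frozen() first")
  }
  m3 <- rep(structure$masses, each = 3L)
  mw <- unclass(as.matrix(hessian)) / sqrt(outer(m3, m3))
  if (project_trans_rot) {
    P <- .eckart_projector(structure)
    mw <- P %*% mw %*% P
    mw <- (mw + t(mw)) / 2
  }
  eig <- eigen(mw, symmetric = TRUE)
  if (any(!is.finite(eig$values))) stop("non-finite eigenvalues")
  freq <- sign(eig$values) * sqrt(abs(eig$values)) * .freq_factor
  keep <- abs(freq) >= zero_tol
  freq <- freq[keep]
  vec <- eig$vectors[, keep, drop = FALSE]
  # exact zeros on frozen coordinates (guard against degenerate mixing)
  if (any(structure$frozen)) {
    idx <- which(rep(structure$frozen, each = 3L))
    vec[idx, ] <- 0
    nrm <- sqrt(colSums(vec^2))
    vec <- sweep(vec, 2, nrm, "/")
  }
  displ <- vec / sqrt(m3)    # un-mass-weight: r = M^{-1/2} q
  if (expect_ts && sum(freq < 0) != 1L)
    stop("expected exactly one imaginary frequency (transition state), ",
         "found ", sum(freq < 0))
  mode_set(freq, displ, structure)
}

# projector removing rigid translations and rotations (mass-weighted basis)
.eckart_projector <- function(structure) {
  n <- length(structure$elements)
  m <- structure$masses
  com <- colSums(structure$coords * m) / sum(m)
  x <- sweep(structure$coords, 2, com)
  sm <- sqrt(m)
  D <- matrix(0, 3 * n, 6)
  for (k in 1:3) D[seq(k, 3 * n, by = 3), k] <- sm
  # rotations: sqrt(m_i) * (e_k x r_i)
  for (i in seq_len(n)) {
    r <- x[i, ]
    rows <- (3 * i - 2):(3 * i)
    D[rows, 4] <- sm[i] * c(0, -r[3], r[2])
    D[rows, 5] <- sm[i] * c(r[3], 0, -r[1])
    D[rows, 6] <- sm[i] * c(-r[2], r[1], 0)
  }
  keep <- sqrt(colSums(D^2)) > 1e-10   # linear molecules: one rotation null
  D <- D[, keep, drop = FALSE]
  Q <- qr.Q(qr(D))
  diag(3 * n) - tcrossprod(Q)
}

#' Kinetic energy distribution of each mode
#'
#' Fills the KED matrix: for mode alpha and atom i,
#' `KED_ia = m_i |r_i|^2 / sum_k m_k |r_k|^2`, where `r_i` is atom i's
#' 3-component displacement within the mode -- the fraction of the mode's
#' kinetic energy carried by atom i. Each column lies in [0, 1] and sums
#' to 1; the statistic is invariant to the normalization of the
#' displacement vectors.
#'
#' @param modes a [mode_set()].
#' @return the same `mode_set` with `$ked` filled (atoms x modes).
#' @export
compute_ked <- function(modes) {
  st <- modes$structure
  n <- length(st$elements)
  d <- modes$displacements
  if (!ncol(d)) { modes$ked <- matrix(0, n, 0); return(modes) }
  atom_of_row <- rep(seq_len(n), each = 3L)
  ked <- apply(d, 2, function(r) {
    w <- st$masses * rowsum(r^2, atom_of_row)[, 1]
    tot <- sum(w)
    if (tot <= 0) stop("mode with zero total displacement")
    w / tot
  })
  modes$ked <- matrix(ked, nrow = n)
  modes
}

#' Define an atom fragment
#'
#' @param name fragment label (e.g. `"CH3"`).
#' @param atoms integer atom indices (1-based).
#' @param n total number of atoms (for range checking), optional.
#' @return object of class `fragment`.
#' @export
fragment <- function(name, atoms, n = NULL) {
  atoms <- as.integer(atoms)
  if (!length(atoms)) stop("empty fragment")
  if (anyDuplicated(atoms)) stop("duplicate atom indices in fragment")
  if (any(atoms < 1) || (!is.null(n) && any(atoms > n)))
    stop("fragment atom index out of range")
  structure(list(name = name, atoms = atoms), class = "fragment")
}

#' Fragment KED of one mode
#'
#' Sum of the per-atom KED over a fragment's atoms for a single mode -- for
#' a transition state's reactive (imaginary) mode this is the fraction of
#' the mode's kinetic energy carried by the fragment (e.g. KED_CH3 of the
#' nascent methyl radical).
#'
#' @param modes a [mode_set()] with KED filled.
#' @param frag a [fragment()] (or integer atom indices).
#' @param mode_index which mode; the default `"imag"` selects the single
#'   imaginary mode (errors if there is not exactly one).
#' @return scalar in [0, 1].
#' @export
fragment_ked <- function(modes, frag, mode_index = "imag") {
  if (inherits(frag, "fragment")) frag <- frag$atoms
  frag <- as.integer(frag)
  if (!length(frag)) stop("empty fragment")
  n <- nrow(modes$ked)
  if (any(frag < 1 | frag > n)) stop("fragment atom index out of range")
  if (identical(mode_index, "imag")) {
    mode_index <- which(modes$freq < 0)
    if (length(mode_index) != 1L)
      stop("mode_index = 'imag' requires exactly one imaginary mode, found ",
           length(mode_index))
  }
  if (mode_index < 1 || mode_index > length(modes$freq))
    stop("invalid mode index")
  if (modes$degenerate[mode_index])
    warning("mode ", mode_index, " lies in a (near-)degenerate pair; ",
            "per-atom KED is not unique within the degenerate subspace")
  sum(modes$ked[frag, mode_index])
}

#' Per-atom kinetic energy from per-mode kinetic energies
#'
#' Aggregates the KED matrix over modes with user-supplied mode kinetic
#' energies: `T_i = sum_alpha KED_ia * T_alpha`. No thermal-population
#' model is assumed; the weights are the caller's.
#'
#' @param modes a [mode_set()] with KED filled.
#' @param mode_energies numeric vector of per-mode kinetic energies
#'   (one per mode, any consistent unit).
#' @return numeric vector of per-atom energies (same unit).
#' @export
atom_kinetic_energy <- function(modes, mode_energies) {
  if (length(mode_energies) != length(modes$freq))
    stop("need one kinetic energy per mode")
  as.numeric(modes$ked %*% mode_energies)
}

#' Read precomputed modes from a delimited file
#'
#' Bypasses diagonalization: expects the `modes` schema of [read_table()]
#' (column `freq_cm1`, then 3n displacement components `d1` ... `d3n`).
#'
#' @param path file path.
#' @param structure the matching [xyz_structure()].
#' @return a [mode_set()].
#' @export
read_modes <- function(path, structure) {
  tab <- read_table(path, "modes")
  dcols <- grep("^d[0-9]+$", names(tab), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
  if (length(dcols) != 3L * length(structure$elements))
    stop("modes file has ", length(dcols), " displacement columns; ",
         "expected 3n = ", 3L * length(structure$elements))
  displ <- t(as.matrix(as.data.frame(tab)[, dcols]))
  mode_set(tab$freq_cm1, displ, structure)
}
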