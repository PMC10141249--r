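#' Construct a molecular structure object
#'
#' A light container for a cluster model: element symbols, isotope-averaged
#' masses, Cartesian coordinates and per-atom frozen flags. Frozen atoms are
#' the fixed framework atoms of a QM cluster model (capping atoms held at
#' crystallographic positions); their degrees of freedom are removed from
#' vibrational analysis by [project_frozen()].
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param frozen logical vector of length n (default all FALSE), or integer
#'   indices of frozen atoms.
#' @param masses numeric vector of masses in amu; defaults to the built-in
#'   standard atomic weights for `elements`.
#' @param label free-text label.
#' @return An object of class `xyz_structure` with fields `elements`,
#'   `masses`, `coords`, `frozen`, `label`.
#' @export
xyz_structure <- function(elements, coords, frozen = NULL, masses = NULL,
                          label = "") {
  coords <- as.matrix(coords)
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(masses)) masses <- atomic_mass(elements)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite, one per atom")
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (is.numeric(frozen)) frozen <- seq_len(n) %in% frozen
  stopifnot(length(frozen) == n)
  if (all(frozen)) stop("all atoms frozen: no free degrees of freedom")
  structure(
    list(elements = elements, masses = masses, coords = coords,
         frozen = frozen, label = label),
    class = "xyz_structure"
  )
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure> %d atoms (%d frozen)%s\n",
              length(x$elements), sum(x$frozen),
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Number of atoms / frozen atoms / free Cartesian DOF
#'
#' @param structure an [xyz_structure()].
#' @return named integer vector `c(n, f, free_dof)` where `free_dof = 3(n-f)`.
#' @export
dof_counts <- function(structure) {
  n <- length(structure$elements)
  f <- sum(structure$frozen)
  c(n = n, f = f, free_dof = 3L * (n - f))
}

#' Read an (extended) XYZ file
#'
#' Standard XYZ layout: first line the atom count, second line a free-text
#' comment, then one `element x y z` line per atom. A trailing token `F` on
#' an atom line marks that atom as frozen.
#'
#' @param path path to the file.
#' @return an [xyz_structure()]; the comment line becomes its `label`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  label <- if (length(lines) >= 2) lines[2] else ""
  if (length(lines) < n + 2)
    stop("XYZ parse error at line ", length(lines) + 1,
         ": expected ", n, " atom lines, file ends early")
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  frozen <- logical(n)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    elements[i] <- tok[1]
    coords[i, ] <- xyz
    frozen[i] <- length(tok) >= 5 && toupper(tok[5]) == "F"
  }
  xyz_structure(elements, coords, frozen = frozen, label = label)
}

#' Write an (extended) XYZ file
#'
#' @param structure an [xyz_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  n <- length(structure$elements)
  body <- vapply(seq_len(n), function(i) {
    sprintf("%-3s %16.8f %16.8f %16.8f%s", structure$elements[i],
            structure$coords[i, 1], structure$coords[i, 2],
            structure$coords[i, 3],
            if (structure$frozen[i]) "  F" else "")
  }, character(1))
  writeLines(c(as.character(n), structure$label, body), path)
  invisible(path)
}
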