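#' Construct a Cartesian Hessian object
#'
#' @param mat 3n x 3n numeric matrix of second derivatives, hartree/bohr^2.
#'   The matrix is always symmetrized as (H + t(H))/2; an asymmetry beyond
#'   `warn_tol` raises a warning, beyond `err_tol` an error.
#' @param structure the matching [xyz_structure()] (optional, used for a
#'   dimension check).
#' @param warn_tol,err_tol asymmetry thresholds (max |H - t(H)|).
#' @return a `cart_hessian`: the symmetrized matrix with a class attribute.
#' @export
cart_hessian <- function(mat, structure = NULL, warn_tol = 1e-6,
                         err_tol = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("Hessian must be square")
  if (nrow(mat) %% 3 != 0) stop("Hessian dimension must be a multiple of 3")
  if (!all(is.finite(mat))) stop("Hessian entries must be finite")
  if (!is.null(structure) && nrow(mat) != 3L * length(structure$elements))
    stop("Hessian dimension ", nrow(mat), " does not match structure (3n = ",
         3L * length(structure$elements), ")")
  asym <- max(abs(mat - t(mat)))
  if (asym > err_tol)
    stop("Hessian asymmetry ", format(asym), " exceeds ", err_tol)
  if (asym > warn_tol)
    warning("Hessian asymmetry ", format(asym), "; symmetrizing")
  mat <- (mat + t(mat)) / 2
  class(mat) <- c("cart_hessian", class(mat))
  mat
}

#' @export
print.cart_hessian <- function(x, ...) {
  cat(sprintf("<cart_hessian> %d x %d (n = %d atoms)\n",
              nrow(x), ncol(x), nrow(x) %/% 3L))
  invisible(x)
}

#' Read a plain-text Cartesian Hessian
#'
#' Format: a header line `natoms N units hartree_bohr2`, then the 3N x 3N
#' matrix in row-major whitespace-separated values (any line wrapping).
#'
#' @param path path to the file.
#' @param structure optional [xyz_structure()] to validate the dimension
#'   against.
#' @inheritParams cart_hessian
#' @return a [cart_hessian()].
#' @export
read_hessian <- function(path, structure = NULL, warn_tol = 1e-6,
                         err_tol = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("Hessian parse error at line 1: empty file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || hdr[1] != "natoms")
    stop("Hessian parse error at line 1: expected 'natoms N units hartree_bohr2'")
  n <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(n) || n < 1)
    stop("Hessian parse error at line 1: bad atom count '", hdr[2], "'")
  vals <- suppressWarnings(as.numeric(unlist(strsplit(
    trimws(lines[-1][nzchar(trimws(lines[-1]))]), "\\s+"))))
  if (anyNA(vals)) stop("Hessian parse error: non-numeric matrix entry")
  d <- 3L * n
  if (length(vals) != d * d)
    stop("Hessian dimension error: header declares ", d, "x", d, " = ",
         d * d, " entries, found ", length(vals))
  mat <- matrix(vals, nrow = d, byrow = TRUE)
  cart_hessian(mat, structure, warn_tol = warn_tol, err_tol = err_tol)
}

#' Write a Cartesian Hessian in the plain-text format of [read_hessian()]
#'
#' @param hessian matrix or [cart_hessian()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hessian <- function(hessian, path) {
  d <- nrow(hessian)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("natoms %d units hartree_bohr2", d %/% 3L), con)
  apply(unclass(hessian), 1, function(row)
    writeLines(paste(sprintf("%.12e", row), collapse = " "), con))
  invisible(path)
}

#' Project frozen-atom degrees of freedom out of a Hessian
#'
#' Orthogonal projection onto the subspace of unfrozen Cartesian coordinates:
#' rows and columns belonging to frozen atoms are zeroed. The projected
#' matrix acquires (at least) 3f zero eigenvalues, so that a subsequent
#' normal-mode analysis yields 3n - 3f vibrations -- the 3n - 24 / 3n - 25
#' counting convention of an 8-frozen-atom cluster model for minima and
#' transition states respectively.
#'
#' @param hessian a [cart_hessian()] (or plain 3n x 3n matrix).
#' @param structure the matching [xyz_structure()] carrying `frozen` flags.
#' @return a [cart_hessian()] with frozen rows/columns zeroed; returned
#'   unchanged when no atom is frozen.
#' @export
project_frozen <- function(hessian, structure) {
  n <- length(structure$elements)
  if (nrow(hessian) != 3L * n)
    stop("Hessian dimension does not match structure")
  if (all(structure$frozen)) stop("all atoms frozen: nothing to analyse")
  if (!any(structure$frozen)) return(cart_hessian(hessian, structure))
  idx <- which(rep(structure$frozen, each = 3L))
  mat <- unclass(as.matrix(hessian))
  mat[idx, ] <- 0
  mat[, idx] <- 0
  cart_hessian(mat, structure)
}
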