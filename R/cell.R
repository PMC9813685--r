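#' Unit-cell description
#'
#' Defines the periodic box on which densities and reflections live: lattice
#' constants in nanometres, inter-axial angles in degrees, and the voxel grid
#' used for real-space maps.  Cubic and hexagonal (gamma = 120) cells are the
#' intended use; any angles in (0, 180) are accepted as long as the resulting
#' cell matrix is non-singular.
#'
#' @param a,b,c lattice constants (nm); `b` and `c` default to `a`.
#' @param alpha,beta,gamma inter-axial angles (degrees).
#' @param grid integer vector of voxel counts per axis, length 1 or 3.
#'   Defaults to 32 voxels per edge.
#' @return an object of class `"unit_cell"`.
#' @examples
#' unit_cell(14.19)                      # cubic, 32^3 voxels
#' unit_cell(8.84, 8.84, 8.43, gamma = 120)  # hexagonal
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90,
                      grid = c(32L, 32L, 32L)) {
  lengths <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(lengths)) || any(lengths <= 0))
    stop("lattice constants must be finite and > 0")
  if (!all(is.finite(angles)) || any(angles <= 0) || any(angles >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  grid <- as.integer(rep_len(grid, 3L))
  if (any(is.na(grid)) || any(grid < 2L))
    stop("grid must contain at least 2 voxels per axis")
  cell <- structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), grid = grid),
    class = "unit_cell")
  # fail early on degenerate angle combinations
  if (!is.finite(det(cell_matrix(cell))) || det(cell_matrix(cell)) <= 0)
    stop("cell angles define a degenerate (non-positive-volume) cell")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%g b=%g c=%g nm, angles %g/%g/%g deg, grid %s\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma,
              paste(x$grid, collapse = "x")))
  invisible(x)
}

#' Fractional-to-Cartesian cell matrix
#'
#' Returns the 3x3 matrix `M` (nm) such that a fractional coordinate `u`
#' maps to the Cartesian position `M %*% u`.  Standard crystallographic
#' orthogonalisation with `a` along x.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  cz <- (ca - cb * cg) / sg
  z3 <- sqrt(max(0, 1 - cb^2 - cz^2))
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * cz, cell$c * z3),
         nrow = 3, ncol = 3)
}

#' Interplanar spacings for Miller indices
#'
#' Computes d-spacings (nm) from the reciprocal metric tensor, so cubic
#' (`d = a / sqrt(h^2 + k^2 + l^2)`) and hexagonal
#' (`1/d^2 = 4/3 (h^2 + hk + k^2)/a^2 + l^2/c^2`) cells are both exact.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer matrix with three columns (or a length-3 vector).
#' @return numeric vector of d-spacings in nm.
#' @examples
#' d_spacing(unit_cell(10), rbind(c(1, 0, 0), c(1, 1, 1)))
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- as_hkl_matrix(hkl)
  M <- cell_matrix(cell)
  G_inv <- solve(crossprod(M))           # reciprocal metric tensor
  q2 <- rowSums((hkl %*% G_inv) * hkl)   # |h*|^2 = 1/d^2
  1 / sqrt(q2)
}

# coerce vector/matrix input to an m x 3 integer matrix
as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3) stop("hkl must have three columns")
  storage.mode(hkl) <- "double"
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  storage.mode(hkl) <- "integer"
  dimnames(hkl) <- NULL
  hkl
}

cells_equal <- function(x, y, tol = 1e-9) {
  all(abs(c(x$a - y$a, x$b - y$b, x$c - y$c,
            x$alpha - y$alpha, x$beta - y$beta, x$gamma - y$gamma)) < tol) &&
    all(x$grid == y$grid)
}
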