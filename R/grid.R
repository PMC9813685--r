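#' Periodic density grid
#'
#' Real-valued scalar field (electron-density contrast, arbitrary units) on
#' the voxel grid of a unit cell.  Voxel `(i, j, k)` (0-based) sits at the
#' fractional coordinate `(i/Na, j/Nb, k/Nc)`, matching the discrete-FFT
#' index convention so that origin shifts are exact lattice translations of
#' the grid.
#'
#' @param cell a [unit_cell()].
#' @param values numeric array with `dim == cell$grid` (or a vector of the
#'   matching length, filled in column-major order).
#' @return an object of class `"density_grid"` with components `cell` and
#'   `values`.
#' @export
density_grid <- function(cell, values) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.null(dim(values))) {
    if (length(values) != prod(cell$grid))
      stop("values length does not match the cell grid")
    values <- array(as.numeric(values), dim = cell$grid)
  } else {
    if (!all(dim(values) == cell$grid))
      stop("values dimensions do not match the cell grid")
    values <- array(as.numeric(values), dim = cell$grid)
  }
  if (!all(is.finite(values))) stop("density values must be finite")
  structure(list(cell = cell, values = values), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "Density grid %s: min %.4g, max %.4g, mean %.3g, sd %.4g\n",
    paste(dim(v), collapse = "x"), min(v), max(v), mean(v), stats::sd(v)))
  invisible(x)
}

#' Fractional voxel coordinates of a grid
#'
#' @param cell a [unit_cell()].
#' @return list of three vectors `x`, `y`, `z` with the fractional
#'   coordinates of voxel centres along each axis.
#' @keywords internal
frac_coords <- function(cell) {
  n <- cell$grid
  list(x = (seq_len(n[1]) - 1) / n[1],
       y = (seq_len(n[2]) - 1) / n[2],
       z = (seq_len(n[3]) - 1) / n[3])
}
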