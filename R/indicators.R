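#' Density-range indicator I_rho
#'
#' The difference between the maximum and minimum electron density in the
#' unit cell.  TPMS-like densities, which vary as gently as the observed
#' amplitudes allow, attain small values; the retrieval loop minimises this
#' quantity and adopts the minimum-`I_rho` iterate as the final structure.
#' Scales linearly with the density (and hence with the amplitudes).
#'
#' @param grid a [density_grid()].
#' @return non-negative scalar.
#' @export
i_rho <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  max(grid$values) - min(grid$values)
}

#' Strictly convex density regions
#'
#' Marks voxels where the 3x3 Hessian of the density has three nonzero
#' eigenvalues of one sign — the strictly convex (or concave) regions,
#' i.e. closed iso-density blobs.  Eigenvalues are obtained in closed form
#' from the spectral-derivative Hessian fields; "nonzero" means
#' `|lambda| > tol * max(|lambda|)` over the whole grid, guarding against
#' the exact zeros of degenerate directions surviving only to round-off.
#' Counting both signs makes the mask invariant under density inversion,
#' matching the Babinet equivalence of candidate structures.
#'
#' @param grid a [density_grid()].
#' @param tol relative eigenvalue tolerance.
#' @return logical array of the grid's dimensions.
#' @export
convex_region <- function(grid, tol = 1e-6) {
  H <- hessian_fields(grid)
  ev <- eigvals_sym3(H$xx$values, H$yy$values, H$zz$values,
                     H$xy$values, H$xz$values, H$yz$values)
  cut <- tol * max(abs(ev$e1), abs(ev$e2), abs(ev$e3))
  mask <- (ev$e1 > cut & ev$e2 > cut & ev$e3 > cut) |
          (ev$e1 < -cut & ev$e2 < -cut & ev$e3 < -cut)
  array(mask, dim = grid$cell$grid)
}

#' Convexity indicator I_K
#'
#' The fraction of total density magnitude lying in strictly convex
#' regions: `sum(|rho|) over C / sum(|rho|) over the cell`, with `C` from
#' [convex_region()].  Dimensionless, in [0, 1], invariant under density
#' scaling and inversion; small for bicontinuous TPMS-like maps (whose
#' saddle-dominated geometry has few closed blobs) and large for maps of
#' isolated convex particles.  The defining functional is pluggable via
#' `region_fun` should an alternative convexity detector be preferred.
#'
#' @param grid a [density_grid()].
#' @param region_fun function returning the convex mask; defaults to
#'   [convex_region()].
#' @return scalar in [0, 1]; 0 for an all-zero grid by convention.
#' @export
i_k <- function(grid, region_fun = convex_region) {
  stopifnot(inherits(grid, "density_grid"))
  total <- sum(abs(grid$values))
  if (total == 0) return(0)
  mask <- region_fun(grid)
  sum(abs(grid$values[mask])) / total
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorised over voxels
# (trigonometric method; robust for the smooth band-limited fields here).
eigvals_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  scale <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / scale; b22 <- (a22 - q) / scale; b33 <- (a33 - q) / scale
  b12 <- a12 / scale; b13 <- a13 / scale; b23 <- a23 / scale
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zero <- p2 <= 0
  if (any(zero)) { e1[zero] <- q[zero]; e2[zero] <- q[zero]; e3[zero] <- q[zero] }
  list(e1 = e1, e2 = e2, e3 = e3)   # e1 >= e2 >= e3
}
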