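#' Synthesise a density grid from phased structure factors
#'
#' Inverse Fourier synthesis: `rho(r) = sum_h F(h) exp(+2 pi i h.r)` with
#' `r` fractional, `F(h) = |F| exp(i phi)` at each stored reflection and the
#' Hermitian mate at `-h`.  All coefficients outside the reflection set are
#' zero, as is `F(000)`, so the returned density has zero mean.  Amplitudes
#' are Fourier coefficients (not voxel sums); the synthesis is therefore
#' independent of the grid size.
#'
#' @param refl a phased [reflection_set()].
#' @param cell optional [unit_cell()] overriding `refl$cell` (must agree in
#'   lattice constants; lets callers synthesise on a finer grid).
#' @return a [density_grid()].
#' @examples
#' cell <- unit_cell(1, grid = 16)
#' r <- reflection_set(cell, rbind(c(1,0,0), c(0,1,0), c(0,0,1)),
#'                     rep(1, 3), rep(0, 3))
#' g <- density_from_factors(r)   # 2(cos 2pi x + cos 2pi y + cos 2pi z)
#' @export
density_from_factors <- function(refl, cell = refl$cell) {
  stopifnot(inherits(refl, "reflection_set"))
  if (is.null(refl$phase)) stop("reflection set has no phases")
  idx <- coef_indices(cell, refl$hkl)
  f <- refl$amplitude * exp(1i * refl$phase)
  arr <- array(0i, dim = cell$grid)
  arr[idx$plus] <- f
  arr[idx$minus] <- Conj(f)
  values <- Re(stats::fft(arr, inverse = TRUE))
  density_grid(cell, values)
}

#' Extract structure factors from a density grid
#'
#' Forward Fourier analysis: returns the discrete Fourier coefficients of
#' the grid at the requested Miller indices, as amplitudes and phases.
#' Because the grid is real the result is Friedel-symmetric by construction.
#'
#' @param grid a [density_grid()].
#' @param hkl integer matrix of Miller indices to extract (no `(0,0,0)`).
#' @return a phased [reflection_set()].
#' @export
factors_from_density <- function(grid, hkl) {
  stopifnot(inherits(grid, "density_grid"))
  hkl <- as_hkl_matrix(hkl)
  if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) cannot be extracted")
  idx <- coef_indices(grid$cell, hkl)
  coefs <- stats::fft(grid$values)[idx$plus] / prod(grid$cell$grid)
  reflection_set(grid$cell, hkl, Mod(coefs), Arg(coefs))
}

#' Raw complex structure factors at given indices
#'
#' Like [factors_from_density()] but returns the complex coefficients in the
#' input row order without canonicalisation — the form the iteration loop
#' and the symmetry projection need.
#'
#' @inheritParams factors_from_density
#' @return complex vector, one coefficient per row of `hkl`.
#' @keywords internal
complex_factors <- function(grid, hkl) {
  idx <- coef_indices(grid$cell, as_hkl_matrix(hkl))
  stats::fft(grid$values)[idx$plus] / prod(grid$cell$grid)
}

#' Second-derivative (Hessian) fields of a periodic density
#'
#' Spectral differentiation: every Fourier coefficient is multiplied by the
#' appropriate `-4 pi^2` frequency product, giving exact derivatives of the
#' band-limited density.  Derivatives are taken with respect to Cartesian
#' coordinates (nm): the fractional-coordinate Hessian is transformed with
#' the cell matrix `M` as `M^-T H M^-1`, which for cubic cells is a uniform
#' `1/a^2` scaling and for hexagonal cells supplies the metric cross terms.
#' Only the eigenvalue signs are consumed downstream, so the overall scale
#' is immaterial.
#'
#' @param grid a [density_grid()].
#' @return named list of six [density_grid()]s: `xx`, `yy`, `zz`, `xy`,
#'   `xz`, `yz` (units nm^-2 times the density unit).
#' @export
hessian_fields <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  cell <- grid$cell
  n <- cell$grid
  coefs <- stats::fft(grid$values)
  k1 <- fft_freqs(n[1]); k2 <- fft_freqs(n[2]); k3 <- fft_freqs(n[3])
  K1 <- array(rep(k1, times = n[2] * n[3]), dim = n)
  K2 <- array(rep(rep(k2, each = n[1]), times = n[3]), dim = n)
  K3 <- array(rep(k3, each = n[1] * n[2]), dim = n)
  ifft_real <- function(mult) {
    Re(stats::fft(coefs * mult, inverse = TRUE)) / prod(n)
  }
  # fractional-coordinate Hessian components
  Hf <- list(ifft_real(-4 * pi^2 * K1 * K1),
             ifft_real(-4 * pi^2 * K2 * K2),
             ifft_real(-4 * pi^2 * K3 * K3),
             ifft_real(-4 * pi^2 * K1 * K2),
             ifft_real(-4 * pi^2 * K1 * K3),
             ifft_real(-4 * pi^2 * K2 * K3))
  B <- solve(t(cell_matrix(cell)))  # M^-T, maps frac gradients to Cartesian
  # H_cart[a,b] = sum_{p,q} B[a,p] Hf[p,q] B[b,q]
  comp <- function(a, b) {
    out <- 0
    pq <- rbind(c(1,1,1), c(2,2,2), c(3,3,3), c(1,2,4), c(1,3,5), c(2,3,6))
    for (r in seq_len(nrow(pq))) {
      p <- pq[r, 1]; q <- pq[r, 2]; s <- pq[r, 3]
      w <- B[a, p] * B[b, q]
      if (p != q) w <- w + B[a, q] * B[b, p]
      if (w != 0) out <- out + w * Hf[[s]]
    }
    density_grid(cell, out)
  }
  list(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
       xy = comp(1, 2), xz = comp(1, 3), yz = comp(2, 3))
}

# signed FFT frequencies 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

# linear indices of +h and -h in the coefficient array; errors on aliasing
coef_indices <- function(cell, hkl) {
  n <- cell$grid
  if (any(abs(hkl) >= matrix(n, nrow(hkl), 3, byrow = TRUE) / 2))
    stop("Miller index component >= N/2: grid too coarse (aliasing)")
  lin <- function(h) {
    i <- h %% matrix(n, nrow(h), 3, byrow = TRUE)
    1 + i[, 1] + n[1] * (i[, 2] + n[2] * i[, 3])
  }
  list(plus = lin(hkl), minus = lin(-hkl))
}
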