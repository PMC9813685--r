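#' Density shift achieving a target positive volume fraction
#'
#' Finds the constant `delta_rho` such that the fraction of voxels with
#' `rho + delta_rho > 0` matches the requested volume fraction `v_p` as
#' closely as the discrete grid allows (within `1/N_total`).  Implemented as
#' the negated `(1 - v_p)` order statistic of the density values: exact on
#' the grid and deterministic.
#'
#' @param grid a [density_grid()].
#' @param v_p target volume fraction of the positive region, in (0, 1).
#' @return the shift `delta_rho` (same units as the density).
#' @examples
#' g <- density_grid(unit_cell(1, grid = 8), seq(-1, 1, length.out = 512))
#' solve_density_shift(g, 0.75)   # ~ +0.5
#' @export
solve_density_shift <- function(grid, v_p) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.finite(v_p) || v_p <= 0 || v_p >= 1)
    stop("v_p must lie strictly between 0 and 1")
  v <- as.vector(grid$values)
  if (max(v) - min(v) <= 0)
    stop("constant density: no shift achieves a fraction strictly in (0, 1)")
  s <- sort(v)
  n <- length(s)
  k <- max(1L, min(n - 1L, as.integer(round((1 - v_p) * n))))
  -s[k]
}

#' Flipping thresholds from the density spread
#'
#' Without a volume-fraction constraint the thresholds are symmetric,
#' `t_plus = k_t * sigma` and `t_minus = -k_t * sigma`, with `sigma` the
#' standard deviation of the (zero-mean) density.  With `v_p` set they
#' become asymmetric: `t_plus = k_t * sigma_plus` with `sigma_plus` the
#' root-mean-square of the shifted density over the non-negative region,
#' and `t_minus = -k_t * sigma_minus` over the negative region (ties at
#' zero count as positive).
#'
#' @param grid a [density_grid()].
#' @param delta_rho constant shift already solved for (0 when `vp_set` is
#'   `FALSE`).
#' @param k_t threshold parameter, > 0 (typically 0.2 to 1.3).
#' @param vp_set whether a volume-fraction constraint is active.
#' @return numeric vector `c(t_plus, t_minus)` with `t_plus > 0 > t_minus`.
#' @export
compute_thresholds <- function(grid, delta_rho = 0, k_t, vp_set = FALSE) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.finite(k_t) || k_t <= 0) stop("k_t must be > 0")
  v <- as.vector(grid$values)
  if (!vp_set) {
    sigma <- sqrt(mean((v - mean(v))^2))
    if (sigma == 0) stop("constant density: thresholds undefined")
    return(c(t_plus = k_t * sigma, t_minus = -k_t * sigma))
  }
  vt <- v + delta_rho
  pos <- vt >= 0
  if (!any(pos) || all(pos))
    stop("empty positive or negative region after the density shift")
  c(t_plus = k_t * sqrt(mean(vt[pos]^2)),
    t_minus = -k_t * sqrt(mean(vt[!pos]^2)))
}

#' Shift-threshold-flip density modification
#'
#' The real-space operator of the retrieval iteration.  With the shifted
#' density `rt = rho + delta_rho`: values inside `[t_minus, t_plus]` pass
#' unchanged; a value above the upper threshold becomes
#' `t_plus - k_f * (rt - t_plus)`; a value below the lower threshold becomes
#' `t_minus + k_f * (t_minus - rt)`.  At `k_f = 0` this clips to the band;
#' at `k_f = 1` it reflects the excursion back across the threshold
#' (classic charge flipping).  Both branches fold the out-of-band excursion
#' toward the admissible band — the reading of the flipping rule consistent
#' with the `k_f = 0` clipping limit.
#'
#' @param grid a [density_grid()].
#' @param k_f flipping parameter, >= 0 (typically 0 to 1).
#' @param t_plus,t_minus upper/lower thresholds, `t_plus > 0 > t_minus`.
#' @param delta_rho constant density shift (0 unless a volume fraction is
#'   being enforced).
#' @return the modified [density_grid()].
#' @examples
#' g <- density_grid(unit_cell(1, grid = 2), c(2, -2, 0.5, -0.5, 2, -2, 0, 0))
#' flip_modify(g, k_f = 1, t_plus = 1, t_minus = -1)
#' @export
flip_modify <- function(grid, k_f, t_plus, t_minus, delta_rho = 0) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.finite(k_f) || k_f < 0) stop("k_f must be >= 0")
  if (!(t_plus > 0 && t_minus < 0))
    stop("thresholds must satisfy t_plus > 0 > t_minus")
  rt <- grid$values + delta_rho
  hi <- rt > t_plus
  lo <- rt < t_minus
  out <- rt
  out[hi] <- t_plus - k_f * (rt[hi] - t_plus)
  out[lo] <- t_minus + k_f * (t_minus - rt[lo])
  density_grid(grid$cell, out)
}
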