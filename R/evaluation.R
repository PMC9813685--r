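#' Phase disagreement at a fixed origin shift
#'
#' Amplitude-weighted normalised phase discrepancy between two phased
#' reflection sets sharing the same indices and amplitudes, with the test
#' phases translated by a candidate origin shift:
#' `sum_h |F(h)| |wrap(phi_test + 2 pi h.shift - phi_ref)| / (pi sum_h |F(h)|)`.
#' Lies in [0, 1]: 0 at perfect agreement, 1 when every (centrosymmetric)
#' sign is flipped.  For centrosymmetric sets it reduces to the
#' amplitude-weighted fraction of sign disagreements.
#'
#' @param test,ref phased [reflection_set()]s over the same hkl set with
#'   matching amplitudes.
#' @param shift fractional origin shift of the test structure (length 3).
#' @return scalar in [0, 1].
#' @export
phase_agreement_at_shift <- function(test, ref, shift = c(0, 0, 0)) {
  al <- align_reflections(test, ref)
  d <- wrap_phase(al$phi_test + 2 * pi * as.vector(al$hkl %*% shift) -
                  al$phi_ref)
  sum(al$w * abs(d)) / (pi * sum(al$w))
}

#' Phase-agreement score R_p
#'
#' The evaluation metric for retrieved phases: the disagreement of
#' [phase_agreement_at_shift()] minimised over every voxel-grid origin
#' shift of the test structure, for both the structure and its Babinet
#' (density-inverted, all phases + pi) twin — amplitudes alone cannot
#' distinguish either freedom, so neither should the score.  `R_p < 0.1`
#' is the customary success criterion.
#'
#' @param test,ref phased [reflection_set()]s over the same hkl set.
#' @return list with `r_p` (scalar in [0, 1]), `shift` (best fractional
#'   origin shift), and `babinet` (`TRUE` if the inverted branch won).
#' @examples
#' bench <- make_benchmark("p_small")
#' r_p(bench$truth, bench$truth)$r_p   # 0
#' @export
r_p <- function(test, ref) {
  al <- align_reflections(test, ref)
  n <- ref$cell$grid
  fx <- (seq_len(n[1]) - 1) / n[1]
  fy <- (seq_len(n[2]) - 1) / n[2]
  fz <- (seq_len(n[3]) - 1) / n[3]
  shifts <- as.matrix(expand.grid(x = fx, y = fy, z = fz))
  base <- al$phi_test - al$phi_ref
  P <- 2 * pi * (al$hkl %*% t(shifts))            # m x n_shifts
  wsum <- pi * sum(al$w)
  score_for <- function(offset) {
    D <- abs(wrap_phase(base + offset + P))
    as.vector(al$w %*% D) / wsum
  }
  s_plain <- score_for(0)
  s_bab <- score_for(pi)
  i1 <- which.min(s_plain); i2 <- which.min(s_bab)
  if (s_plain[i1] <= s_bab[i2]) {
    list(r_p = s_plain[i1], shift = unname(shifts[i1, ]), babinet = FALSE)
  } else {
    list(r_p = s_bab[i2], shift = unname(shifts[i2, ]), babinet = TRUE)
  }
}

# Match two phased reflection sets row-by-row (canonical Friedel keys);
# errors on mismatched index sets or inconsistent amplitudes.
align_reflections <- function(test, ref) {
  stopifnot(inherits(test, "reflection_set"), inherits(ref, "reflection_set"))
  if (is.null(test$phase) || is.null(ref$phase))
    stop("both reflection sets must carry phases")
  idx <- match(hkl_key(ref$hkl), hkl_key(test$hkl))
  if (anyNA(idx) || n_reflections(test) != n_reflections(ref))
    stop("reflection sets do not share the same hkl set")
  amp_t <- test$amplitude[idx]
  if (any(abs(amp_t - ref$amplitude) > 1e-6 * (1 + ref$amplitude)))
    stop("reflection sets do not share amplitudes")
  list(hkl = ref$hkl, w = ref$amplitude,
       phi_test = test$phase[idx], phi_ref = ref$phase)
}
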