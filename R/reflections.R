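#' Reflection set: indexed structure-factor amplitudes and optional phases
#'
#' The diffraction-side state of the method: a list of independent Miller
#' indices with observed amplitudes `|F_obs|` and, when known, phases in
#' radians.  One representative per Friedel pair is stored (for a real
#' density `F(-h)` is the complex conjugate of `F(h)`, so the mate carries
#' no information); if both mates are supplied they are checked for
#' consistency and collapsed.  `(0,0,0)` is excluded: the mean density
#' cannot be observed, so all maps synthesised from a reflection set have
#' zero mean.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer matrix (m x 3) of Miller indices, or length-3 vector.
#' @param amplitude non-negative amplitudes, one per row of `hkl`.
#' @param phase optional phases in radians (wrapped into (-pi, pi]).
#' @return an object of class `"reflection_set"` with components `cell`,
#'   `hkl` (canonical Friedel representatives), `amplitude`, `phase`
#'   (or `NULL`), and `d` (interplanar distances, nm).
#' @examples
#' cell <- unit_cell(10)
#' reflection_set(cell, rbind(c(1,0,0), c(0,1,0)), c(1, 2))
#' @export
reflection_set <- function(cell, hkl, amplitude, phase = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  hkl <- as_hkl_matrix(hkl)
  m <- nrow(hkl)
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) != m) stop("amplitude length must match hkl rows")
  if (!all(is.finite(amplitude)) || any(amplitude < 0))
    stop("amplitudes must be finite and non-negative")
  if (!is.null(phase)) {
    phase <- wrap_phase(as.numeric(phase))
    if (length(phase) != m) stop("phase length must match hkl rows")
    if (!all(is.finite(phase))) stop("phases must be finite")
  }
  if (any(rowSums(abs(hkl)) == 0))
    stop("(0,0,0) is not admissible: F(000) cannot be observed")

  key <- hkl_key(hkl)
  if (anyDuplicated(key)) stop("duplicate hkl entries")

  # collapse Friedel mates onto the canonical representative
  rep_sign <- friedel_sign(hkl)
  chkl <- hkl * rep_sign
  cphase <- if (is.null(phase)) NULL else phase * rep_sign
  ckey <- hkl_key(chkl)
  first <- !duplicated(ckey)
  if (!all(first)) {
    idx <- match(ckey[!first], ckey[first])
    if (any(abs(amplitude[!first] - amplitude[first][idx]) >
            1e-8 * (1 + amplitude[first][idx])))
      stop("Friedel mates present with unequal amplitudes")
    if (!is.null(cphase)) {
      # phases of vanishing coefficients are numerical noise; only check
      # mates that carry weight
      dphi <- wrap_phase(cphase[!first] - cphase[first][idx])
      weighty <- amplitude[!first] > 1e-8 * max(amplitude)
      if (any(abs(dphi[weighty]) > 1e-6))
        stop("Friedel mates present with inconsistent phases")
    }
  }
  chkl <- chkl[first, , drop = FALSE]
  amplitude <- amplitude[first]
  if (!is.null(cphase)) cphase <- cphase[first]

  d <- d_spacing(cell, chkl)
  # sampling rule: grid spacing must be <= d_min/2, i.e. N >= 2 a / d_min
  need <- ceiling(2 * c(cell$a, cell$b, cell$c) / min(d))
  if (any(cell$grid < need))
    warning(sprintf(
      "grid %s is below the d_min/2 sampling rule (needs >= %s divisions)",
      paste(cell$grid, collapse = "x"), paste(need, collapse = "x")))

  structure(list(cell = cell, hkl = chkl, amplitude = amplitude,
                 phase = cphase, d = d),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf(
    "Reflection set: %d independent reflections, d range %.4g-%.4g nm, %s\n",
    nrow(x$hkl), min(x$d), max(x$d),
    if (is.null(x$phase)) "amplitudes only" else "with phases"))
  print(x$cell)
  invisible(x)
}

#' @export
as.data.frame.reflection_set <- function(x, ...) {
  df <- data.frame(h = x$hkl[, 1], k = x$hkl[, 2], l = x$hkl[, 3],
                   amplitude = x$amplitude, d = x$d)
  if (!is.null(x$phase)) df$phase <- x$phase
  df
}

#' Number of independent reflections
#' @param refl a [reflection_set()].
#' @return integer count of stored (Friedel-independent) reflections.
#' @export
n_reflections <- function(refl) nrow(refl$hkl)

#' Expand a reflection set to include Friedel mates
#'
#' Appends `-h` with equal amplitude and negated phase for every stored
#' reflection.  Mostly useful for tests and for writing complete lists.
#'
#' @param refl a [reflection_set()].
#' @return a `"reflection_set"` holding both mates (still no `(0,0,0)`).
#' @export
expand_friedel <- function(refl) {
  stopifnot(inherits(refl, "reflection_set"))
  hkl <- rbind(refl$hkl, -refl$hkl)
  amp <- c(refl$amplitude, refl$amplitude)
  ph <- if (is.null(refl$phase)) NULL else c(refl$phase, -refl$phase)
  out <- refl
  out$hkl <- hkl
  out$amplitude <- amp
  out$phase <- if (is.null(ph)) NULL else wrap_phase(ph)
  out$d <- d_spacing(refl$cell, hkl)
  out
}

#' Drop phases from a reflection set
#'
#' Returns the amplitude-only "observed" view of a phased set.
#'
#' @param refl a [reflection_set()].
#' @return the same set with `phase = NULL`.
#' @export
strip_phases <- function(refl) {
  stopifnot(inherits(refl, "reflection_set"))
  refl$phase <- NULL
  refl
}

#' Attach phases to a reflection set
#' @param refl a [reflection_set()].
#' @param phase numeric phases (radians), one per independent reflection.
#' @return the set with `phase` set (wrapped into (-pi, pi]).
#' @export
set_phases <- function(refl, phase) {
  stopifnot(inherits(refl, "reflection_set"))
  phase <- as.numeric(phase)
  if (length(phase) != n_reflections(refl))
    stop("phase length must match the number of independent reflections")
  if (!all(is.finite(phase))) stop("phases must be finite")
  refl$phase <- wrap_phase(phase)
  refl
}

# sign that maps each hkl row onto its canonical Friedel representative:
# first nonzero index component positive
friedel_sign <- function(hkl) {
  s <- sign(hkl[, 1])
  z <- s == 0
  s[z] <- sign(hkl[z, 2])
  z <- s == 0
  s[z] <- sign(hkl[z, 3])
  as.integer(s)
}

hkl_key <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3], sep = ",")

# wrap radians into (-pi, pi]
wrap_phase <- function(x) {
  w <- x - 2 * pi * floor(x / (2 * pi) + 0.5)  # [-pi, pi)
  w[w == -pi] <- pi
  w
}
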