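#' Space-group symmetry operators
#'
#' A set of `(R, t)` operators acting on fractional coordinates as
#' `u -> R u + t`.  Used to constrain initial phases by projecting the
#' structure factors onto the symmetry-consistent subspace (a generic
#' replacement for tabulated space-group phase relations).  The set is
#' validated on construction: the identity must be present and the set must
#' be closed under composition modulo lattice translations.
#'
#' @param ops list of operators, each a list with `R` (3x3 integer matrix)
#'   and `t` (length-3 fractional translation; defaults to zero).
#' @return an object of class `"symmetry_ops"`.
#' @examples
#' symmetry_ops(list(list(R = diag(3)), list(R = -diag(3))))  # P-1
#' @export
symmetry_ops <- function(ops) {
  if (!is.list(ops) || length(ops) == 0) stop("ops must be a non-empty list")
  ops <- lapply(ops, function(o) {
    R <- as.matrix(o$R)
    if (!all(dim(R) == c(3, 3)) || any(R != round(R)))
      stop("each R must be a 3x3 integer matrix")
    storage.mode(R) <- "integer"
    if (abs(det(R)) != 1) stop("each R must have determinant +/-1")
    t <- if (is.null(o$t)) c(0, 0, 0) else as.numeric(o$t)
    if (length(t) != 3 || !all(is.finite(t))) stop("each t must be length 3")
    list(R = R, t = t %% 1)
  })
  key <- function(R, t) paste(c(R, round(t %% 1, 9)), collapse = ",")
  keys <- vapply(ops, function(o) key(o$R, o$t), "")
  if (anyDuplicated(keys)) stop("duplicate operators")
  if (!key(diag(3L), c(0, 0, 0)) %in% keys)
    stop("identity operator missing")
  for (g1 in ops) for (g2 in ops) {
    Rc <- g1$R %*% g2$R
    tc <- (as.vector(g1$R %*% g2$t) + g1$t) %% 1
    if (!key(Rc, tc) %in% keys)
      stop("operator set not closed under composition (mod lattice)")
  }
  structure(list(ops = ops), class = "symmetry_ops")
}

#' @export
print.symmetry_ops <- function(x, ...) {
  cat(sprintf("Symmetry: %d operators\n", length(x$ops)))
  invisible(x)
}

#' Inversion-only operator set
#'
#' Convenience constructor for the centrosymmetric group \{1, -1\}; as an
#' initial-phase constraint it is equivalent to restricting structure
#' factors to real values.
#' @return a [symmetry_ops()] object.
#' @export
sym_inversion <- function() {
  symmetry_ops(list(list(R = diag(3L)), list(R = -diag(3L))))
}

# Project complex structure factors onto the symmetry-invariant subspace:
# F_sym(h) = (1/|G|) sum_g F(h R_g^-1) exp(+2 pi i (h R_g^-1) . t_g),
# the Fourier-space image of group-averaging the density.  Coefficients
# whose symmetry mates fall outside the stored set (or its Friedel mates)
# contribute zero.
project_factors <- function(refl, f, symmetry) {
  hkl <- refl$hkl
  key <- hkl_key(hkl)
  out <- rep(0 + 0i, length(f))
  for (g in symmetry$ops) {
    Rinv <- round(solve(g$R))
    hg <- hkl %*% Rinv                       # rows h R_g^-1
    phase <- exp(2i * pi * as.vector(hg %*% g$t))
    i1 <- match(hkl_key(hg), key)            # mate stored directly
    i2 <- match(hkl_key(-hg), key)           # mate stored as Friedel partner
    fg <- rep(0 + 0i, length(f))
    fg[!is.na(i1)] <- f[i1[!is.na(i1)]]
    use2 <- is.na(i1) & !is.na(i2)
    fg[use2] <- Conj(f[i2[use2]])
    out <- out + fg * phase
  }
  out / length(symmetry$ops)
}

# Orbit ids of reflections under the symmetry group (Friedel-collapsed):
# reflections whose indices map onto each other share an id.
symmetry_orbits <- function(refl, symmetry) {
  hkl <- refl$hkl
  key <- hkl_key(hkl)
  orbit_key <- vapply(seq_len(nrow(hkl)), function(i) {
    mates <- do.call(rbind, lapply(symmetry$ops, function(g) {
      hg <- as.integer(hkl[i, ] %*% g$R)
      rbind(hg, -hg)
    }))
    min(hkl_key(mates))
  }, "")
  match(orbit_key, unique(orbit_key))
}
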