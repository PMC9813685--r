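#' Control parameters for charge-flipping retrieval
#'
#' Collects every tunable of the iteration, in the style of `glm.control()`.
#' The flipping parameter `k_f` (0 to 1: 0 clips at the thresholds, 1
#' reflects across them) and threshold parameter `k_t` (typically 0.2 to
#' 1.3, in units of the density spread sigma) are varied periodically over
#' the run; their periods should differ so the two cycles do not lock
#' together (a warning is issued if they coincide).
#'
#' @param iterations number of iterations per run.
#' @param kf schedule for the flipping parameter: a [schedule_spec()] or a
#'   numeric `c(mean, width, period)`.
#' @param kt schedule for the threshold parameter, same forms.
#' @param v_p optional target volume fraction of the positive-density
#'   region, in (0, 1); when set, a constant density shift is solved each
#'   iteration and the thresholds become one-sided RMS values.
#' @param real_f logical; constrain structure factors to real values
#'   (centrosymmetry), keeping phases in \{0, pi\} throughout.
#' @param symmetry optional [symmetry_ops()]; initial phases are projected
#'   onto the symmetry-consistent subspace (and per-iteration if
#'   `project_every = TRUE`).
#' @param project_every logical; re-apply the symmetry projection at every
#'   iteration instead of only at initialisation (off by default — the
#'   iteration is left free to keep or break the symmetry on its own).
#' @param waveform waveform passed to [schedule_spec()] when `kf`/`kt` are
#'   given numerically.
#' @return an object of class `"flip_control"`.
#' @examples
#' flip_control(iterations = 700, kf = c(0.5, 0.5, 29), kt = c(0.75, 0.25, 19))
#' @export
flip_control <- function(iterations = 700L,
                         kf = c(0.5, 0.5, 29),
                         kt = c(0.75, 0.25, 19),
                         v_p = NULL, real_f = FALSE,
                         symmetry = NULL, project_every = FALSE,
                         waveform = "sine") {
  as_schedule <- function(x) {
    if (inherits(x, "schedule_spec")) return(x)
    if (is.numeric(x) && length(x) == 3)
      return(schedule_spec(x[1], x[2], x[3], waveform = waveform))
    stop("schedules must be schedule_spec objects or c(mean, width, period)")
  }
  kf <- as_schedule(kf); kt <- as_schedule(kt)
  if (!is.finite(iterations) || iterations < 1)
    stop("iterations must be a positive integer")
  if (kf$period == kt$period)
    warning("k_f and k_t schedules share a period; cycles will lock together")
  if (!is.null(v_p) && (!is.finite(v_p) || v_p <= 0 || v_p >= 1))
    stop("v_p must lie strictly between 0 and 1")
  if (!is.null(symmetry)) stopifnot(inherits(symmetry, "symmetry_ops"))
  structure(list(iterations = as.integer(iterations), kf = kf, kt = kt,
                 v_p = v_p, real_f = isTRUE(real_f), symmetry = symmetry,
                 project_every = isTRUE(project_every)),
            class = "flip_control")
}

#' Random initial phases
#'
#' Draws uniform phases on (-pi, pi] per independent reflection (Friedel
#' mates are implicit and negated).  With `real_f` the draw is restricted
#' to \{0, pi\}; with a symmetry group the random factors are projected onto
#' the symmetry-consistent subspace and amplitudes are averaged over
#' symmetry orbits.
#'
#' @param refl a [reflection_set()] with amplitudes.
#' @param seed optional integer seed (sets the RNG when given).
#' @param real_f restrict phases to \{0, pi\}.
#' @param symmetry optional [symmetry_ops()].
#' @return a phased [reflection_set()].
#' @export
init_phases <- function(refl, seed = NULL, real_f = FALSE, symmetry = NULL) {
  stopifnot(inherits(refl, "reflection_set"))
  if (!is.null(seed)) set.seed(seed)
  m <- n_reflections(refl)
  phi <- pi - stats::runif(m, 0, 2 * pi)       # uniform on (-pi, pi]
  if (!is.null(symmetry)) {
    f <- refl$amplitude * exp(1i * phi)
    fs <- project_factors(refl, f, symmetry)
    ok <- Mod(fs) > 1e-12 * max(refl$amplitude, 1e-300)
    phi[ok] <- Arg(fs[ok])                     # keep the random draw where
    orbit <- symmetry_orbits(refl, symmetry)   # the projection annihilates
    refl$amplitude <- stats::ave(refl$amplitude, orbit)
  }
  if (real_f) phi <- ifelse(cos(phi) >= 0, 0, pi)
  set_phases(refl, phi)
}

# Precomputed state for the iteration loop: coefficient indices, grid dims.
flip_engine <- function(refl) {
  idx <- coef_indices(refl$cell, refl$hkl)
  list(idx = idx, dims = refl$cell$grid, n_total = prod(refl$cell$grid))
}

# One iteration on raw vectors.  phases: current phases per independent
# reflection; returns list(phases, i_rho, rho) where rho is the step-(i)
# density (synthesised from the *input* phases).
flip_step <- function(eng, amp, phases, k_f, k_t, v_p, real_f) {
  arr <- array(0i, dim = eng$dims)
  f <- amp * exp(1i * phases)
  arr[eng$idx$plus] <- f
  arr[eng$idx$minus] <- Conj(f)
  rho <- Re(stats::fft(arr, inverse = TRUE))
  i_rho <- max(rho) - min(rho)

  # step (ii): optional shift, thresholds, flip.  A flat map (all
  # amplitudes zero) has no spread to threshold: pass it through unchanged.
  delta <- 0
  if (i_rho > 0) {
    if (!is.null(v_p)) {
      s <- sort.int(rho, method = "quick")
      k <- max(1L, min(eng$n_total - 1L,
                       as.integer(round((1 - v_p) * eng$n_total))))
      delta <- -s[k]
      rt <- rho + delta
      pos <- rt >= 0
      if (any(pos) && !all(pos)) {
        t_plus <- k_t * sqrt(mean(rt[pos]^2))
        t_minus <- -k_t * sqrt(mean(rt[!pos]^2))
      } else {                                 # degenerate tie plateau
        sigma <- sqrt(mean(rt^2))
        t_plus <- k_t * sigma
        t_minus <- -t_plus
      }
    } else {
      rt <- rho
      sigma <- sqrt(mean(rt^2))                # mean density is 0
      t_plus <- k_t * sigma
      t_minus <- -t_plus
    }
    hi <- rt > t_plus
    lo <- rt < t_minus
    rt[hi] <- t_plus - k_f * (rt[hi] - t_plus)
    rt[lo] <- t_minus + k_f * (t_minus - rt[lo])
  } else {
    rt <- rho
  }

  # steps (iii)+(iv): Fourier analysis, amplitude replacement
  f_calc <- stats::fft(rt)[eng$idx$plus] / eng$n_total
  if (real_f) {
    sgn <- sign(Re(f_calc))
    prev <- ifelse(cos(phases) >= 0, 1, -1)
    sgn[sgn == 0] <- prev[sgn == 0]            # tie-break: keep old sign
    new_phases <- ifelse(sgn > 0, 0, pi)
  } else {
    new_phases <- Arg(f_calc)
    dead <- Mod(f_calc) == 0
    new_phases[dead] <- phases[dead]           # undefined phase: keep old
  }
  list(phases = new_phases, i_rho = i_rho, rho = rho)
}

#' Run one charge-flipping iteration
#'
#' Exposes a single pass of the four-step cycle — Fourier synthesis,
#' shift/threshold/flip modification, Fourier analysis, amplitude
#' replacement — for inspection and testing.  The reported `i_rho` is the
#' density range of the step-(i) map synthesised from the input phases.
#'
#' @param refl a phased [reflection_set()]; amplitudes are taken as
#'   `|F_obs|` and conserved.
#' @param k_f,k_t flipping and threshold parameters for this pass.
#' @param v_p optional positive-region volume fraction.
#' @param real_f keep structure factors real (phases in \{0, pi\}).
#' @return list with `refl` (updated phases), `i_rho`, and `density`
#'   (the step-(i) [density_grid()]).
#' @export
flip_iterate <- function(refl, k_f, k_t, v_p = NULL, real_f = FALSE) {
  stopifnot(inherits(refl, "reflection_set"))
  if (is.null(refl$phase)) stop("reflection set has no phases")
  eng <- flip_engine(refl)
  st <- flip_step(eng, refl$amplitude, refl$phase, k_f, k_t, v_p, real_f)
  list(refl = set_phases(refl, st$phases), i_rho = st$i_rho,
       density = density_grid(refl$cell, st$rho))
}

#' Charge-flipping phase retrieval
#'
#' The main fitting function.  Starting from random phases, the four-step
#' cycle is repeated `control$iterations` times with periodically varying
#' `k_f` and `k_t`; the density-range indicator `I_rho` is recorded at each
#' iteration and the returned structure is the one attaining the minimum
#' `I_rho` over the whole run (earliest iteration on ties).  Observed
#' amplitudes are conserved exactly throughout; unobserved coefficients are
#' held at zero.
#'
#' @param refl a [reflection_set()] with the observed amplitudes (phases,
#'   if present, are ignored).
#' @param control a [flip_control()].
#' @param seed integer seed for the random initial phases.
#' @return an object of class `"charge_flip"` with components `phases`
#'   (best phases, radians), `density` (best-map [density_grid()]), `i_rho`
#'   (its density range), `iteration` (0-based index of the best cycle),
#'   `trace` (data frame: iteration, i_rho, k_f, k_t), plus the inputs.
#'   Methods: [print()], [summary()], [plot()], [coef()], [fitted()].
#' @examples
#' bench <- make_benchmark("p_small")
#' fit <- charge_flip(bench$observed,
#'                    flip_control(iterations = 100, real_f = TRUE), seed = 1)
#' r_p(fitted_phases(fit), bench$truth)$r_p
#' @seealso [charge_flip_runs()] for independent repeats,
#'   [exhaustive_sign_search()] for the enumeration oracle.
#' @export
charge_flip <- function(refl, control = flip_control(), seed = NULL) {
  stopifnot(inherits(refl, "reflection_set"),
            inherits(control, "flip_control"))
  state <- init_phases(strip_phases(refl), seed = seed,
                       real_f = control$real_f, symmetry = control$symmetry)
  eng <- flip_engine(state)
  amp <- state$amplitude
  phases <- state$phase
  n_it <- control$iterations
  trace_i <- numeric(n_it); trace_kf <- numeric(n_it); trace_kt <- numeric(n_it)
  best <- Inf; best_phases <- phases; best_rho <- NULL; best_iter <- 0L
  for (j in seq_len(n_it) - 1L) {
    k_f <- schedule_value(control$kf, j)
    k_t <- schedule_value(control$kt, j)
    st <- flip_step(eng, amp, phases, k_f, k_t, control$v_p, control$real_f)
    trace_i[j + 1L] <- st$i_rho
    trace_kf[j + 1L] <- k_f
    trace_kt[j + 1L] <- k_t
    if (st$i_rho < best) {
      best <- st$i_rho
      best_phases <- phases                    # phases that produced the map
      best_rho <- st$rho
      best_iter <- j
    }
    phases <- st$phases
    if (control$project_every && !is.null(control$symmetry)) {
      f <- amp * exp(1i * phases)
      fs <- project_factors(state, f, control$symmetry)
      ok <- Mod(fs) > 1e-12 * max(amp, 1e-300)
      phases[ok] <- Arg(fs[ok])
      if (control$real_f) phases <- ifelse(cos(phases) >= 0, 0, pi)
    }
  }
  structure(list(refl = strip_phases(refl), control = control, seed = seed,
                 phases = best_phases,
                 density = density_grid(state$cell, best_rho),
                 i_rho = best, iteration = best_iter,
                 trace = data.frame(iteration = seq_len(n_it) - 1L,
                                    i_rho = trace_i, k_f = trace_kf,
                                    k_t = trace_kt)),
            class = "charge_flip")
}

#' Retrieved phases as a reflection set
#'
#' @param fit a `"charge_flip"` object.
#' @return the observed [reflection_set()] carrying the retrieved phases.
#' @export
fitted_phases <- function(fit) {
  stopifnot(inherits(fit, "charge_flip"))
  set_phases(fit$refl, fit$phases)
}

#' Independent retrieval runs
#'
#' Repeats [charge_flip()] with seeds `seed, seed + 1, ...` and returns the
#' results sorted by their best `I_rho` — the multi-start protocol used to
#' summarise success rates (runs reaching `R_p < 0.1` against a reference).
#'
#' @param refl a [reflection_set()] with observed amplitudes.
#' @param control a [flip_control()].
#' @param runs number of independent runs.
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @return an object of class `"charge_flip_set"`: a list with `results`
#'   (list of `"charge_flip"`, ascending `i_rho`) and `seeds`.
#' @export
charge_flip_runs <- function(refl, control = flip_control(), runs = 100L,
                             seed = 1L) {
  stopifnot(runs >= 1)
  seeds <- as.integer(seed) + seq_len(runs) - 1L
  results <- lapply(seeds, function(s) charge_flip(refl, control, seed = s))
  ord <- order(vapply(results, `[[`, 0, "i_rho"))
  structure(list(results = results[ord], seeds = seeds, control = control),
            class = "charge_flip_set")
}

#' Exhaustive sign enumeration for centrosymmetric data
#'
#' The brute-force oracle: for a centrosymmetric reflection set (phases
#' restricted to signs) every sign assignment is enumerated, the density
#' synthesised, and the indicators computed.  The first reflection's sign
#' is fixed positive by default, which absorbs the global density inversion
#' (Babinet-equivalent assignments produce identical indicator values), so
#' `2^(m-1)` candidates are evaluated for `m` independent reflections.
#' Practical only for small `m`; the iterative method exists precisely
#' because this count explodes.
#'
#' @param refl a [reflection_set()] with amplitudes.
#' @param max_bits refuse to enumerate more than `2^max_bits` assignments.
#' @param fix_first fix the first sign `+` (Babinet deduplication).
#' @param compute_ik also compute `I_K` per assignment (slower).
#' @return an object of class `"sign_search"`: list with `signs` (matrix,
#'   one row per assignment), `i_rho`, `i_k` (or `NA`), ascending by
#'   `i_rho`.
#' @export
exhaustive_sign_search <- function(refl, max_bits = 16L, fix_first = TRUE,
                                   compute_ik = TRUE) {
  stopifnot(inherits(refl, "reflection_set"))
  m <- n_reflections(refl)
  if (m > max_bits)
    stop(sprintf("%d independent reflections exceed max_bits = %d",
                 m, max_bits))
  bits <- if (fix_first) m - 1L else m
  n_assign <- 2L^bits
  eng <- flip_engine(refl)
  amp <- refl$amplitude
  signs <- matrix(1L, nrow = n_assign, ncol = m)
  i_rho_v <- numeric(n_assign)
  i_k_v <- rep(NA_real_, n_assign)
  for (a in seq_len(n_assign)) {
    code <- a - 1L
    s <- rep(1L, m)
    if (bits > 0) {
      free <- if (fix_first) 2:m else 1:m
      s[free] <- 1L - 2L * bitwAnd(bitwShiftR(code, seq_len(bits) - 1L), 1L)
    }
    signs[a, ] <- s
    arr <- array(0i, dim = eng$dims)
    f <- amp * s
    arr[eng$idx$plus] <- f
    arr[eng$idx$minus] <- f                   # real coefficients: conj = self
    rho <- Re(stats::fft(arr, inverse = TRUE))
    i_rho_v[a] <- max(rho) - min(rho)
    if (compute_ik)
      i_k_v[a] <- i_k(density_grid(refl$cell, rho))
  }
  ord <- order(i_rho_v)
  structure(list(signs = signs[ord, , drop = FALSE], i_rho = i_rho_v[ord],
                 i_k = i_k_v[ord], hkl = refl$hkl, fix_first = fix_first),
            class = "sign_search")
}

#' @export
print.sign_search <- function(x, ...) {
  cat(sprintf(
    "Sign search: %d assignments over %d reflections; best I_rho %.6g\n",
    nrow(x$signs), ncol(x$signs), x$i_rho[1]))
  invisible(x)
}
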