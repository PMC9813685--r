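# tpmsflip

Crystallographic phase retrieval for materials whose electron density
organises on a **triply periodic minimal surface (TPMS)** — lyotropic
liquid-crystal (LLC) bicontinuous cubic phases, mesoporous silicas and
related bicontinuous soft matter.

## The problem

Small-angle diffraction from these phases yields a handful of
structure-factor amplitudes |F(**h**)| (often 8–50 independent
reflections) and no phases φ(**h**), so the electron density

ρ(**r**) = Σ_h |F(**h**)| e^{iφ(**h**)} e^{2πi **h**·**r**}

cannot be reconstructed directly.  Classical direct methods assume
atomic-resolution data; disordered mesophases offer nothing of the sort.
What they do offer is a strong geometric prior: their density varies
gently along the surface and its two labyrinths, so among all phase
combinations the *true* one tends to minimise the spread of the density.

## The method

`tpmsflip` implements an iterative charge-flipping variant driven by that
prior.  With observed amplitudes fixed, each cycle:

1. synthesises ρ from the current phases (unobserved coefficients and
   F(000) held at zero, hence mean ρ = 0);
2. modifies the map with a **two-sided shift-threshold-flip** operator:
   with the shifted density ρ̃ = ρ + Δρ and thresholds
   t₊ = k_t σ₊, t₋ = −k_t σ₋,

   - ρ̃ in [t₋, t₊] → unchanged,
   - ρ̃ > t₊ → t₊ − k_f (ρ̃ − t₊),
   - ρ̃ < t₋ → t₋ + k_f (t₋ − ρ̃);

   k_f = 0 clips at the thresholds, k_f = 1 reflects across them.
   Δρ ≠ 0 only when a target volume fraction v_p of positive density is
   being enforced (then σ₊/σ₋ are one-sided RMS values, otherwise
   σ₊ = σ₋ = σ, the global standard deviation);
3. Fourier-analyses the modified map; and
4. restores |F_obs| while keeping the new phases (optionally projecting
   onto real structure factors for centrosymmetric data).

k_f and k_t are varied periodically (defaults k_f = 0.5 ± 0.5 with
period 29, k_t = 0.75 ± 0.25 with period 19) to keep the search out of
local minima.  Progress is monitored by **I_ρ = max ρ − min ρ**; the
iterate with the smallest I_ρ is the reported structure.  A second
indicator **I_K** — the fraction of density magnitude in strictly convex
regions, detected by uniform-sign eigenvalues of the spectral Hessian —
ranks candidate structures (TPMS-like maps score low; blob-like maps
score high).  Retrieved phases are scored against a reference by
**R_p ∈ [0, 1]**, an amplitude-weighted phase discrepancy minimised over
all origin shifts and the Babinet (contrast-inverted) twin; R_p < 0.1 is
the customary success criterion.

For small centrosymmetric problems `exhaustive_sign_search()` enumerates
every sign assignment outright, providing an independent oracle for the
iteration.  A synthetic generator builds ground-truth TPMS densities
(nodal P/D/G approximants, two-level contrast, tunable volume fraction
and interface softness) and derives reflection sets from them, so the
whole pipeline is testable without any external data.

## Worked example

Retrieve a phytantriol/water-like double gyroid (18 independent
reflections of the {211} and {220} families, membrane volume fraction
0.66) from its amplitudes alone:

```r
library(tpmsflip)

bench <- make_benchmark("g_mid")    # observed amplitudes + hidden truth
bench$observed
#> Reflection set: 18 independent reflections, d range 3.093-3.571 nm, amplitudes only
#> Unit cell: a=8.748 b=8.748 c=8.748 nm, angles 90/90/90 deg, grid 32x32x32

fit <- charge_flip(bench$observed, flip_control(iterations = 700), seed = 1)
summary(fit, reference = bench$truth)
#> Charge-flipping phase retrieval
#>   18 independent reflections, 700 iterations, seed 1
#>   best I_rho 1.28565 at iteration 177
#>   indicators: I_rho 1.28565, I_K 0.09381, |C|/N 0.04688
#>   R_p 0.03575 (Babinet twin, shift 0.8438 0.7812 0.9688) -> success (R_p < 0.1)
```

The run attains its minimum density range I_ρ at iteration 177; the
retrieved phases agree with the ground truth to R_p = 0.036 — well below
the 0.1 success threshold — once the arbitrary origin shift and contrast
inversion are factored out.  `plot(fit)` shows the I_ρ trace and the
parameter schedules; `coef(fit)` returns the phases; `fitted(fit)` the
density map.  `charge_flip_runs()` repeats the run over many seeds and
`summary(runs, reference = ...)` tabulates the success count, mirroring
the usual "n of 100 runs with R_p < 0.1" benchmark summaries.

A command-line interface wraps the same functions:

```sh
inst/exec/tpmsflip simulate --name g_mid --out-prefix g
inst/exec/tpmsflip retrieve g_observed.hkl --runs 20 --iterations 700 \
    --truth g_truth.hkl --out-prefix run
inst/exec/tpmsflip evaluate g_truth.hkl run_best.hkl
```

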