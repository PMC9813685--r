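---
title: "Phase retrieval for TPMS-like structures: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase retrieval for TPMS-like structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmsflip)
```

## The structural prior

Bicontinuous cubic mesophases — lipid/water cubic phases, mesoporous
silicas, block-copolymer networks — arrange their density on a triply
periodic minimal surface (P, D, G, or the hexagonal H family).  Their
diffraction patterns contain few reflections and no phases.  The prior
this package exploits is that the *true* density of such a phase is
spatially gentle: molecules diffuse along the surface and the labyrinths,
smearing contrast, so the density range in the cell is close to the
smallest achievable given the observed amplitudes.  The retrieval
problem becomes: among all phase assignments consistent with
$|F_\mathrm{obs}|$, find one that minimises the density spread.

## The iteration

Writing $\rho_n$ for the map at cycle $n$ (synthesised from the current
phases with all unobserved coefficients, including $F(000)$, at zero —
hence $\bar\rho = 0$ always), the cycle is:

1. **Synthesis.** $\rho_n(\mathbf r) = \sum_{\mathbf h} F_n(\mathbf h)
   e^{2\pi i \mathbf h\cdot\mathbf r}$ on a $32^3$ voxel grid.
2. **Modification.** With $\tilde\rho = \rho_n + \Delta\rho$ and
   thresholds $t_+ = k_t\sigma_+ > 0 > t_- = -k_t\sigma_-$:
   in-band values pass unchanged; $\tilde\rho > t_+$ becomes
   $t_+ - k_f(\tilde\rho - t_+)$; $\tilde\rho < t_-$ becomes
   $t_- + k_f(t_- - \tilde\rho)$.
3. **Analysis.** Fourier transform of the modified map.
4. **Projection.** Amplitudes are reset to $|F_\mathrm{obs}|$ on the
   observed set, all other coefficients to zero; phases are kept (or,
   with the centrosymmetry constraint, reduced to the sign of the real
   part).

The density-range indicator $I_\rho = \max\rho_n - \min\rho_n$ is logged
every cycle and the minimum-$I_\rho$ iterate is returned.  Ties go to the
earliest iteration, making the selection deterministic.

Two wordings of the flipping rule are conceivable for the lower branch;
the literal "threshold minus the excursion" would move density *away*
from the admissible band.  We implement the reflection-toward-interior
form above, the only reading consistent with flipping's purpose and with
the $k_f = 0$ clipping limit (`flip_modify()` documents this).

## Parameters

| Parameter | Meaning | Default | Range used |
|---|---|---|---|
| `k_f` | flip strength: 0 = clip, 1 = reflect | 0.5 ± 0.5, period 29 | 0–1 |
| `k_t` | threshold in units of the density spread σ | 0.75 ± 0.25, period 19 | 0.2–1.3 |
| `iterations` | cycles per run | 700 | 200–7000 |
| `v_p` | target positive-volume fraction | unset | (0, 1) |
| `real_f` | restrict phases to {0, π} | off | — |

Both schedule periods are deliberately coprime-ish; equal periods lock
the two cycles together and are flagged with a warning.  Fixed
parameters converge to local minima far more often — periodic variation
is what lets runs escape them; the waveform itself (sine by default;
triangle and square available) matters much less than the sweep through
the $(k_f, k_t)$ plane, so it is pluggable rather than fixed.

When the positive-region volume fraction of the target is far from 0.5,
the symmetric thresholds misjudge which side of the density to compress;
setting `v_p` shifts the zero level each cycle (an exact order-statistic
solve, not an iterative root find) and switches the thresholds to
one-sided RMS values.  The shifted map is what continues through the
cycle; the constant lands in $F(000)$, which step 4 discards anyway.

With `real_f`, a vanishing real part leaves the sign undefined; the
previous sign is kept.  Equally, a coefficient with zero magnitude in
the general case keeps its previous phase.

## Indicators and evaluation

$I_\rho$ is scale-covariant (doubling the amplitudes doubles it) and
blind to origin shifts and inversion.  $I_K$ is the fraction of density
magnitude in strictly convex regions — voxels where all three
eigenvalues of the Hessian share a sign.  The Hessian is computed
spectrally (the maps are band-limited by construction, so spectral
derivatives are exact) and transformed to Cartesian axes with the cell
metric, which for cubic cells is a uniform scale and for hexagonal cells
supplies the cross terms; only eigenvalue *signs* are consumed either
way.  Eigenvalues come from the closed-form symmetric 3×3 solution,
vectorised over voxels; "nonzero" means $|\lambda| >
10^{-6}\max|\lambda|$ over the grid, guarding against degenerate
directions that vanish only analytically.  Counting both signs (convex
and concave) makes $I_K$ invariant under contrast inversion, as any
indicator compared across Babinet twins must be.  The exact published
functional behind $I_K$ is not reproduced here; the implemented
definition preserves every property used downstream (scale-free, in
$[0,1]$, small for bicontinuous maps, large for blob maps) and
`i_k(region_fun = ...)` accepts a replacement detector.

$R_p$ scores phase agreement: the amplitude-weighted mean of
$|\mathrm{wrap}(\varphi_\mathrm{test} + 2\pi\mathbf h\cdot\mathbf s -
\varphi_\mathrm{ref})|/\pi$, minimised over all $32^3$ grid origin
shifts $\mathbf s$ and over the Babinet twin (all phases $+\pi$), giving
a value in $[0,1]$ that is 0 for equivalent structures and 1 for a
centrosymmetric set with every sign flipped.  For centrosymmetric data
it reduces to the amplitude-weighted fraction of sign disagreements.
The search is exhaustive over voxel translations — exact for
grid-representable structures and sub-second at these sizes; sub-voxel
refinement is deliberately out of scope, so an unconstrained solution
sitting between voxels can carry a small residual $R_p$ (empirically
$\lesssim 0.05$, well under the 0.1 success threshold).  Like the
enumeration below, it is exact-Babinet: handedness inversion of a chiral
structure is *not* absorbed, matching the convention of counting mirror
solutions separately.

## The synthetic generator

`nodal_density()` builds ground truths from the standard nodal
approximants ($\cos X + \cos Y + \cos Z$ for P, etc.), binarised to a
two-level contrast and smoothed by a periodic Gaussian (`softness`, in
voxels; default 1 — roughly the diffuse-interface width real phases
show).  Two partitions are available because the field contains both
structure classes:

* **surface** (default): the TPMS side is the membrane slab
  $|f| \le t$; the network side is *both* labyrinths.  This is the
  double-network geometry of the lyotropic cubic phases and of most
  templated silicas, and for G it is centrosymmetric, as the real
  phases are.
* **labyrinth**: the TPMS side is the one-sided super-level set
  $f > t$ — a single-network, generally chiral structure (the srs-net
  silica case).

`volume_fraction` sets the TPMS-side fraction; type-I contrast puts the
high density there, type II the low density (so for type II the quoted
fraction is the low-density fraction, the convention used for lipid
phases).  Thresholding a symmetric grid involves large tie plateaus
(symmetry orbits share nodal values exactly); ties are excluded
wholesale so that symmetry-equivalent voxels are never split, which can
leave the achieved fraction a plateau (up to ~1%) short of the request —
preferable to breaking centrosymmetry, which phase errors of order
$10^{-3}$ rad would already destroy for the oracle tests.

`derive_reflections()` turns a truth map into an observed set: one
representative per Friedel pair, complete down to `d_min` and above an
amplitude floor.  Completeness matters: an "observed" set made of the
$N$ *strongest* reflections cherry-picked across a deep resolution
sphere zeroes mid-strength coefficients inside the sphere, and the
ground truth then ceases to be the $I_\rho$ minimiser — the retrieval
faithfully finds a better-scoring wrong structure.  Real reflection
lists are complete to their resolution limit, and the benchmarks follow
suit:

* `p_small` — P-surface single labyrinth, $a = 14.19$ nm, fraction
  0.43, families {100}+{111} (7 reflections; the following shells are
  ~10× weaker).  Centrosymmetric; small enough that
  `exhaustive_sign_search()` (64 deduplicated assignments) provides the
  oracle, and constructed so the truth is the strict $I_\rho$ minimiser
  with a ~5% gap to the first non-equivalent assignment.
* `g_mid` — double gyroid, $a = 8.748$ nm, membrane fraction 0.66,
  families {211}+{220} (18 reflections) — the phytantriol-like regime
  on which the multi-start success rate is measured.
* `d_mid` — double diamond, $a = 6.474$ nm, fraction 0.57 (25
  reflections).
* `blob_control` — eight periodic Gaussian blobs, width 4 voxels so its
  positive-region fraction (~0.36) matches the gyroid truth (~0.38):
  the matched-volume-fraction negative control for $I_K$.

What the generator does **not** emulate: measurement noise (a
multiplicative amplitude-noise option exists but is off by default, as
the oracle comparisons need exact amplitudes), incomplete/overlapping
powder peaks, multiple scattering, and the full space-group symmetry of
real samples (nodal approximants carry slightly different extinction
patterns than the exact surfaces).  Passing tests therefore demonstrate
the *algorithmic* claims — convergence to the minimum-$I_\rho$ structure,
indicator behaviour, metric properties — not robustness to experimental
error.

## Numerical choices

* Grid: $32^3$ voxels, voxel centres at $i/N$, satisfying the
  $d_\mathrm{min}/2$ sampling rule for every benchmark (the rule is
  checked at construction and violations warn rather than fail).
* Fourier convention: $\rho(\mathbf r) = \sum F(\mathbf h)
  e^{+2\pi i\mathbf h\cdot\mathbf r}$, $F$ as coefficients (forward
  transform divided by the voxel count), making amplitudes
  grid-size-independent.  The origin-shift search uses the same sign.
* $\Delta\rho$: order-statistic solve, exact to $1/N_\mathrm{total}$ on
  continuous densities.
* Region boundary for $\sigma_\pm$: ties at $\tilde\rho = 0$ count as
  positive (measure zero on real data).
* Degenerate inputs: an all-zero amplitude set synthesises a flat map,
  passes through the modification unchanged and keeps its phases — a
  silent fixed point rather than an error.
* Symmetry projection: given explicit operators, initial factors are
  orbit-averaged in reciprocal space (a generic stand-in for tabulated
  space-group phase relations); with {1, −1} this reduces exactly to the
  real-$F$ constraint.  The projection is applied at initialisation
  only — the iteration is left free to keep or break the symmetry — with
  a per-cycle option for experimentation.

## Problem sizes

The shipped experiments use 20 independent runs per condition (200
iterations for the oracle comparison, 700 for the unconstrained gyroid),
64–2048-assignment enumerations, and 100–10000-draw Monte-Carlo checks
of the metric properties; each completes in seconds to ~1 minute on a
single core.  The multi-start summaries report "successes out of 20";
at larger compute budgets the same protocol is conventionally run with
100 starts, and `charge_flip_runs(runs = 100)` does exactly that.

## Known limitations

* No sub-voxel origin refinement in $R_p$ (see above).
* The symmetry projection validates closure but does not generate
  groups from generators or parse space-group symbols.
* Hexagonal support covers the metric (d-spacings, Hessian transform,
  map IO); no hexagonal benchmark fixture ships.
* `exhaustive_sign_search()` is $O(2^m)$ by design; `max_bits` (default
  16) refuses anything larger.
* $F(000)$ — the absolute density scale — is unrecoverable in principle;
  all outputs are contrasts about a zero mean.
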