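---
title: "Methods: individual-based metapopulations on fragmented lattice landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based metapopulations on fragmented lattice landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmeta)
```

`fragmeta` simulates a semelparous, individual-based metapopulation on an
`L × L` lattice with periodic boundary conditions (a torus, to minimize
finite-size effects) and measures persistence, abundance and spatial
synchrony under controlled degrees of habitat fragmentation. This vignette
is the package's own account of the model, the numerical choices behind it,
and what the test suite does and does not establish.

## The landscape layer

A landscape is a boolean habitat mask on the torus; cells are unit squares,
so habitat cover `h` is the habitat-cell fraction. Four constructors span a
fragmentation gradient:

* `make_homogeneous(L)` — all habitat (`h = 1`).
* `make_fragmented(L, alpha_e, threshold)` — a *neutral landscape*: a
  zero-mean, unit-variance Gaussian random field with exponential covariance
  `exp(-d/alpha_e)` is thresholded, `habitat ⇔ ε(x) > threshold`. Expected
  cover is `1 - pnorm(threshold)`; `alpha_e` sets fragment size. With
  `alpha_e = 3` on `L = 60`, thresholds 1.1 and 0.5 give the "highly"
  (`h ≈ 0.10–0.13`) and "lowly" (`h ≈ 0.25–0.30`) fragmented classes.
* `make_regular_grid(L, patch_side, spacing)` — the classical abstraction:
  identical square patches at equal nearest-neighbour torus distances
  (`spacing` must divide `L`); `(1, 3)` on `L = 60` gives 400 unit patches,
  `h = 11%`, comparable to the highly fragmented class.
* `subsample_landscape(x, size)` — a uniformly random (wrapping) square
  window, returned with the periodic boundary reset, for studying landscape
  area effects.

**Threshold direction.** We classify the *upper* tail as habitat. The
alternative (`direction = "<"`) is exposed as an argument, but the upper-tail
convention is the one consistent with the intended covers: for a
unit-variance field, `P(ε > 1.1) ≈ 0.136` and `P(ε > 0.5) ≈ 0.309`, matching
the highly/lowly fragmented cover ranges above, whereas the lower tail would
give covers of 0.86/0.69. On a torus the choice is otherwise symmetric.

**Aggregation geometry.** `aggregate_habitat()` re-packs the `H` habitat
cells row-major into a block of side `ceiling(sqrt(H))` anchored at the
origin (last row partial). This is deterministic, area-preserving,
idempotent, and maximally compact up to one partial row; on a torus any
anchor is equivalent up to translation. Comparing persistence with and
without aggregation isolates *fragmentation per se* — the effect of habitat
configuration at fixed habitat amount.

## Sampling Gaussian random fields exactly

Both the landscape generator and the environmental noise need stationary
Gaussian fields with exponential covariance on the torus. Because the
minimum-image covariance matrix of a stationary field on a torus is
block-circulant, it is diagonalised by the 2-D DFT: `spectral_density()`
computes the FFT of the covariance evaluated at minimum-image lags, and
`grf_sample()` colours white noise in the frequency domain,

```
field = Re( IFFT( sqrt(S) * FFT(W) ) ),   W ~ iid N(0, 1),
```

which is *exact* (not an approximation on an embedded larger torus) at
`O(L² log L)` per draw — a Cholesky factorisation of the `L² × L²` covariance
would be `O(L⁶)`. One subtlety: the exponential covariance wrapped onto the
torus is not guaranteed nonnegative-definite, so small negative spectral
values can occur; they are clamped to zero and the removed mass is reported
(`attr(, "clamped_mass")`). For the parameterizations used here the clamped
mass is zero to well below `10⁻³` of the total, so the realised covariance is
indistinguishable from the target at Monte Carlo precision (the test suite
checks lags 1, 3, 6 at `L = 32`, `scale = 3`, 2000 samples, ±0.05).

`scale = Inf` is a dedicated branch — a single global `Normal(0, variance)`
draw — not a large-`scale` approximation, and `variance = 0` returns the zero
field, so both degenerate regimes are exact.

## The generation cycle

`step_generation()` applies six stages in fixed order; all randomness comes
from R's global RNG so a seed makes the step bit-reproducible.

1. **Regional stochasticity.** `log μ(x) = μ₀ + g(x)` with `g` a GRF of
   variance `σᵣ²` and scale `αᵣ`, resampled independently each generation
   (no temporal autocorrelation). `αᵣ = ∞` is globally synchronized noise
   (one shared draw); `σᵣ² = 0` makes fecundity the constant `exp(μ₀)`.
   `μ₀` is the mean of *log* fecundity — median fecundity `exp(μ₀)`, with no
   `−σ²/2` correction; the default `μ₀ = log(1.1)` means a median of 1.1
   offspring. On the arithmetic scale `μ₀ = log(1.1) ≈ 0.095` would be an
   implausible mean fecundity, which is why the log-scale convention is the
   ecologically sensible reading.
2. **Reproduction.** Each adult produces `Poisson(μ)` propagules using the
   fecundity of its *own* cell (reproduction precedes dispersal; evaluating
   at the landing site instead would entangle dispersal with habitat quality
   sampling), then dies.
3. **Dispersal.** Independent `Normal(0, α_d²)` displacement per axis,
   wrapped modulo `L`; `α_d = ∞` disperses uniformly.
4. **Matrix mortality.** Propagules in non-habitat cells die and do not
   compete.
5. **Local density.** Surviving propagules are binned to cells and the
   counts are circularly convolved (FFT) with a discretized bivariate
   Gaussian kernel of scale `α_c`, normalized to sum 1, so `nᵢ` is a
   propagule density per unit area evaluated at propagule `i`'s cell.
6. **Establishment.** Independent Bernoulli with `eᵢ = 1/(1 + b nᵢ)` given
   the realized densities (no sequential depletion — `eᵢ` depends only on
   `nᵢ`).

Positions are continuous; habitat membership and density are cell-level.
This hybrid keeps the dispersal kernel exact while making occupancy and
abundance well defined on habitat cells (cell area 1).

**The mass-action limit.** With `α_c = ∞` every propagule sees the global
density `P/L²` (total surviving propagules over *total* lattice area). This
is the exact limit of the sum-1 competition kernel, which spreads mass over
the whole torus, and it is the choice under which the expected dynamics
reduce, for any cover `h`, to the Beverton–Holt map
`N' = N μ h / (1 + b N μ h)` in density-per-total-area units — the
`mean_field_step()` comparator. (Normalising by habitat area instead would
cancel `h` from the competition term and break that equivalence.)

**How close is the reduction?** Exactly unbiased over one generation at the
process level, but the mean-field map is the deterministic skeleton of a
stochastic process: because the map is concave in the propagule count, the
demographic (Poisson/Bernoulli) fluctuations induce a Jensen-type downward
correction of order `1/N` in the stationary mean. On the homogeneous
`60 × 60` landscape (`N* ≈ 1636`) the measured gap is ~0.5–1% — within 3 SE
of the mean trajectory in the acceptance check, and bounded at 2% by a
regression guard. It is a property of the model pair, not a defect of either
implementation.

**Initialization.** `init_population(land, density)` places
`round(density·L²)` individuals — a density per unit of *total* landscape
area, so a fixed density means a fixed propagule rain regardless of cover —
uniformly over habitat cells (matrix placement would be death at `t = 0`,
adding a cover-dependent transient with no dynamical content).

## Experiment drivers

All drivers expand one top-level seed into per-replicate child seeds by a
fixed multiplicative-congruential scheme (`child_seed()`), so replicate `k`
is reproducible in isolation and paired designs (e.g. aggregation
comparisons) share seeds across arms.

**Persistence** (`run_persistence`): replicates run until extinction or the
cap `t_max` (default `5 × 10⁵`). Replicates reaching the cap are *censored
at the cap* and enter the mean at `t_max`; the censored fraction is always
reported, so a censoring-heavy mean is visibly a lower bound. The headline
persistence analysis uses globally synchronized noise (`αᵣ = ∞`).

**Abundance** (`run_abundance`): tracks `N_t` and iterates the stochastic
Beverton–Holt comparator per replicate, driven by the *same* realized
per-generation mean fecundities as the simulation (for `αᵣ = ∞` this is
exactly the shared global draw), which removes the comparator's own
fecundity-sampling noise from the comparison. Quasistationarity is
operationalized as the final 50 generations of the run.

**Synchrony** (`synchrony_correlogram`): the lattice is tiled by `m × m`
sampling sites (`m` divides `L`; contiguous tiles, so site centres are `m`
apart — intersite distance ≈ 2 for `m = 2`). Per replicate and site, local
occupancy is the fraction of the site's habitat cells occupied and local
abundance the occupant count per habitat cell; habitat-free sites are
excluded. Synchrony of a site pair is the Pearson correlation of these
values *across replicates at the final generation*; replicates extinct at
that generation are dropped (an all-zero replicate carries no synchrony
information — measurement is conditional on persistence), and pairs are
binned at `[l − 0.5, l + 0.5]` around each requested distance. Sites that
are constant across replicates yield undefined correlations and are excluded
from bin means.

**Calibration** (`calibrate_mu0`): synchrony is confounded when most sites
are empty or saturated, so `μ₀` is adjusted to hold the mean global
population size in a target band (default 1000 ± 200 on `L = 60`). The
search is bisection on `μ₀` with common random numbers across evaluations;
the initial guess inverts the mean-field fixed point
`N* = (μh − 1)/(bμh)`. Achieved size is monotone in `μ₀` over the viable
range, so bracketing is reliable; failure to bracket raises an error with
the evaluation path attached.

## Defaults and tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `L` | lattice side (cells) | 60 | cell spacing = 1 length unit |
| `alpha_e` | landscape correlation scale | 3 | fragment size |
| `threshold` | habitat threshold | 1.1 / 0.5 | high/low fragmentation |
| `alpha_d`, `alpha_c` | dispersal / competition scale | 1, `= alpha_d` | `∞` = mass action; decoupled for sensitivity work |
| `b` | competition strength | 0.2 | `eᵢ = 1/(1+b·nᵢ)` |
| `mu0` | mean log-fecundity | `log(1.1)` | median fecundity 1.1 |
| `sigma_r2` | noise variance | 0.5 | also 1, 2 in persistence scans |
| `alpha_r` | noise correlation scale | `∞` | 1.5, 6, `∞` in abundance/synchrony scans |
| `t_max` | extinction cap | `5 × 10⁵` | censored at cap |
| `init_density` | initial individuals per unit area | 1000/3600 | 5000/3600 for abundance/synchrony runs |

## Problem sizes used by the test suite

Full-scale experiments (3000 persistence replicates, 5000 synchrony
iterations) are configuration values for production runs; the shipped tests
use scaled ensembles chosen so the whole suite runs in a few minutes while
each check retains clear statistical resolution:

* landscape covers: 500 realizations per threshold at `L = 60`;
* GRF covariance: 2000 samples at `L = 32`;
* mean-field equivalence: 500 paired replicates × 50 generations;
* calibration: 100 pilot replicates × 50 generations, verified on a fresh
  100–200 replicate ensemble;
* qualitative regressions (fixed seeds): the noise–persistence "falling
  wedge" on a homogeneous 6 × 6 lattice (300 replicates, cap 10⁴); the
  resident/migrant persistence reversal between the highly fragmented and
  homogeneous 60 × 60 landscapes (30 replicates, cap 2000); aggregation
  never shortening resident persistence (30 paired replicates).

## What the synthetic landscapes do and do not emulate

The thresholded-GRF generator produces binary habitat/matrix mosaics with
tunable cover and fragment scale and no directional anisotropy. It does not
emulate: matrix-quality gradients (the matrix is uniformly lethal),
vector/GIS geometries, non-square lattices, anisotropic or non-exponential
correlation, temporal landscape change, or non-Euclidean (e.g. network)
dispersal distances. Tests passing on these landscapes therefore speak to
the *mechanisms* of fragmentation responses, not to any particular empirical
landscape. Likewise the demographic model excludes overlapping generations,
iteroparity, interspecific interactions, temporal autocorrelation of the
environment, and behaviourally plastic dispersal.

## Numerical notes and degenerate inputs

* FFT convolution and GRF synthesis are exact up to floating point; the
  convolution is verified against direct `O(P²)` pairwise summation at
  `10⁻⁸`.
* `alpha → 0⁺` degenerates gracefully: the dispersal kernel collapses to the
  parent position and the competition kernel to a delta at lag 0.
* Wrapping guards against the floating-point edge case `x %% L == L`.
* `N = 0` is absorbing everywhere; empty populations, empty landscapes and
  `variance = 0` fields short-circuit to exact results.
* Censored persistence means are monotone under a stricter cap by
  construction (paired child seeds), which the suite asserts.
* Config files round-trip doubles exactly (YAML at precision 17); result
  CSVs embed the config hash (MD5 of a canonical JSON dump) and seed.

## Known limitations

Persistence means under heavy censoring are lower bounds, not estimates, of
the true mean time to extinction. Synchrony estimates need enough surviving
replicates (the driver errors below 2; several dozen is a practical
minimum). The Beverton–Holt comparator deliberately ignores space; on
fragmented landscapes its divergence from the simulation is the scientific
signal, not an error to be minimized. Finally, fecundity is evaluated at the
parent's cell; if offspring instead sampled the environment where they land,
the interaction of dispersal with regional stochasticity could differ
quantitatively (the choice matters only when `αᵣ` is comparable to `α_d`).
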