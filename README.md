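# fragmeta

Individual-based metapopulation dynamics on arbitrarily fragmented lattice
landscapes.

## The problem

Classical metapopulation theory predicts how a set of spatially disjunct
populations persists through a balance of local extinctions and
recolonizations — but it was mostly built on simple, discrete patch networks.
Real landscapes are irregular mosaics of variably sized, possibly contiguous
habitat fragments. `fragmeta` is a simulator for exploring how that
difference matters: it runs an individual-based model on an `L × L` periodic
lattice whose habitat layout ranges from homogeneous, through irregularly
fragmented neutral landscapes, to a regular patch grid, and measures
metapopulation persistence, abundance and spatial synchrony at the level of
individuals rather than patches. It is aimed at spatial ecologists and
modellers studying fragmentation, the SLOSS/habitat-aggregation question, and
the interaction of dispersal with spatially correlated environmental
stochasticity (the Moran effect).

## The model

**Landscapes.** Fragmented landscapes are thresholded Gaussian random fields:
a zero-mean, unit-variance field ε with exponential covariance
`cov(ε(x), ε(x′)) = exp(−d(x, x′)/αₑ)` is sampled exactly on the torus
(circulant/FFT spectral synthesis; `d` is the minimum-image distance) and a
cell is habitat where `ε > threshold`, so the expected habitat cover is
`1 − Φ(threshold)`. Homogeneous landscapes, regular grids of equidistant unit
patches, random square subsamples (with the periodic boundary reset) and
habitat *aggregation* (re-packing all habitat into one compact square, area
held fixed — fragmentation per se) are also provided.

**One generation.** Each semelparous adult at cell x produces a
Poisson(μ(x)) number of propagules and dies. Log-fecundity is a spatially
correlated field resampled every generation (regional stochasticity):
`log μ(x) = μ₀ + g(x)`, `cov(g(x), g(x′)) = σᵣ² exp(−d(x, x′)/αᵣ)`.
Propagules disperse by a bivariate Gaussian kernel with covariance `α²I`
(α = ∞: uniform), die instantly in the matrix, and establish with probability
`eᵢ = 1/(1 + b·nᵢ)`, where the local propagule density `nᵢ` is the cell-binned
propagule count convolved with a Gaussian competition kernel of the same
scale α (normalized to sum 1). Species with small α are "residents", with
large α "migrants".

**Mean-field comparator.** In the mass-action limit the model reduces to the
stochastic Beverton–Holt map `N_{t+1} = N_t μ_t h / (1 + b N_t μ_t h)` with
`h` the habitat cover and `log μ_t ~ Normal(μ₀, σᵣ²)`, which the package
iterates alongside every abundance experiment.

## Worked example

Residents versus migrants on a highly fragmented landscape, and the effect
of aggregating the same amount of habitat into one block:

```r
library(fragmeta)
set.seed(101)
land <- make_fragmented(60, alpha_e = 3, threshold = 1.1)
land
#> <landscape> 60 x 60 torus, habitat cover 0.131 (470 cells), type: fragmented

sp_res <- species_params(alpha_d = 1)    # "resident": local dispersal/competition
sp_mig <- species_params(alpha_d = Inf)  # "migrant": mass-action limit
env <- env_params(mu0 = log(1.1), sigma_r2 = 0.5, alpha_r = Inf)

run_persistence(land, sp_res, env, reps = 100, t_max = 2000, seed = 1)
#> <persistence_result> 100 replicates: mean time 20.4 generations (0% censored at 2000)
run_persistence(land, sp_mig, env, reps = 100, t_max = 2000, seed = 1)
#> <persistence_result> 100 replicates: mean time 4.3 generations (0% censored at 2000)

run_persistence_aggregated(land, sp_res, env, reps = 100, t_max = 2000,
                           seed = 1)$aggregated
#> <persistence_result> 100 replicates: mean time 67.7 generations (0% censored at 2000)
```

On this habitat-poor landscape the resident (mean 20.4 generations) outlives
the migrant (4.3), which wastes most propagules in the matrix — a reversal of
the classical intuition that mobility protects metapopulations. Aggregating
the same 470 habitat cells into one compact patch more than triples resident
persistence (67.7), quantifying the cost of fragmentation per se.

A command-line interface wraps the same drivers:

```sh
Rscript inst/cli/fragmeta.R generate-landscape --type fragmented --size 60 \
    --alpha-e 3 --threshold 1.1 --seed 101 --out mask.txt
Rscript inst/cli/fragmeta.R persistence --seed 1 --reps 100 --t-max 2000 --out times.csv
```

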