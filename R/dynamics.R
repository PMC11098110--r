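#' Species parameters: dispersal and competition scales, competition strength
#'
#' In the main analyses a single scale `alpha` governs both dispersal and
#' competition ("residents" small alpha, "migrants" large); the two scales
#' can be decoupled for sensitivity analyses.  `alpha = Inf` is the
#' mass-action limit: uniform dispersal and global density dependence.
#'
#' @param alpha_d dispersal scale in lattice units (> 0 or `Inf`).
#' @param alpha_c competition scale; defaults to `alpha_d`.
#' @param b competition strength (>= 0); establishment probability of a
#'   propagule at local density `n` is `1 / (1 + b * n)`.
#' @return object of class `"species_params"`.
#' @export
species_params <- function(alpha_d = 1, alpha_c = alpha_d, b = 0.2) {
  check_scale(alpha_d, "alpha_d")
  check_scale(alpha_c, "alpha_c")
  stopifnot(is.numeric(b), length(b) == 1L, b >= 0)
  structure(list(alpha_d = alpha_d, alpha_c = alpha_c, b = b),
            class = "species_params")
}

#' Environment parameters: regional stochasticity of fecundity
#'
#' Log-fecundity at cell x in each generation is
#' `log mu(x) = mu0 + g(x)` where `g` is a zero-mean Gaussian random field
#' with covariance `sigma_r2 * exp(-d / alpha_r)`, resampled independently
#' every generation (no temporal autocorrelation).  `alpha_r = Inf` is
#' globally synchronized environmental stochasticity: one shared draw per
#' generation.  `mu0` is the mean of log-fecundity (so the median fecundity
#' is `exp(mu0)`; no -sigma^2/2 correction is applied).
#'
#' @param mu0 mean log-fecundity (default `log(1.1)`).
#' @param sigma_r2 variance of regional stochasticity (>= 0; 0 means a
#'   deterministic fecundity `exp(mu0)` everywhere).
#' @param alpha_r spatial scale of regional stochasticity (> 0 or `Inf`).
#' @return object of class `"env_params"`.
#' @export
env_params <- function(mu0 = log(1.1), sigma_r2 = 0.5, alpha_r = Inf) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L,
            is.numeric(sigma_r2), length(sigma_r2) == 1L, sigma_r2 >= 0)
  check_scale(alpha_r, "alpha_r")
  structure(list(mu0 = mu0, sigma_r2 = sigma_r2, alpha_r = alpha_r),
            class = "env_params")
}

#' Population of individuals at continuous torus coordinates
#'
#' @param xy N x 2 numeric matrix of positions in `[0, L)^2` (wrapped
#'   modulo `L` on construction).
#' @param L lattice side length.
#' @return object of class `"population"` with elements `xy`, `L`.
#' @export
population <- function(xy, L) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  if (nrow(xy)) xy <- wrap_torus(xy, L)
  structure(list(xy = xy, L = L), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d individuals on a %d x %d torus\n",
              nrow(x$xy), x$L, x$L))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [population()].
#' @return integer count.
#' @export
pop_size <- function(pop) nrow(pop$xy)

#' Initialize a population of spatially randomized individuals
#'
#' Places `round(density * L^2)` individuals uniformly over habitat cells
#' (uniform across habitat cells, uniform within a cell).  The count is
#' scaled by total landscape area, matching the convention of a fixed
#' density "per unit area" of landscape; placement is restricted to habitat
#' because matrix placement would be instant death.
#'
#' @param land a [landscape()].
#' @param density individuals per unit landscape area (>= 0), e.g.
#'   `1000/3600` on a 60 x 60 lattice for 1,000 individuals.
#' @return a [population()].
#' @export
init_population <- function(land, density) {
  stopifnot(inherits(land, "landscape"), density >= 0)
  L <- land$L
  n <- round(density * L * L)
  hab <- which(land$mask)
  if (n > 0 && length(hab) == 0L) {
    warning("landscape has no habitat; returning an empty population")
    n <- 0L
  }
  if (n == 0L) return(population(matrix(numeric(0), ncol = 2L), L))
  cells <- hab[sample.int(length(hab), n, replace = TRUE)]
  i <- ((cells - 1L) %% L)          # 0-based row
  j <- ((cells - 1L) %/% L)         # 0-based col
  xy <- cbind(i + stats::runif(n), j + stats::runif(n))
  population(xy, L)
}

#' Sample one generation's fecundity field
#'
#' Draws `log mu(x) = mu0 + g(x)` with `g` a zero-mean Gaussian random field
#' of variance `sigma_r2` and scale `alpha_r` (see [env_params()]).
#'
#' @param env an [env_params()].
#' @param L lattice side length.
#' @param sqrt_spectrum optional precomputed square-root spectrum for the
#'   regional-stochasticity field (ignored when `alpha_r = Inf` or
#'   `sigma_r2 = 0`).
#' @return L x L matrix of positive fecundities.
#' @export
sample_fecundity_field <- function(env, L, sqrt_spectrum = NULL) {
  stopifnot(inherits(env, "env_params"))
  if (env$sigma_r2 == 0) return(matrix(exp(env$mu0), L, L))
  g <- grf_sample(L, scale = env$alpha_r, variance = env$sigma_r2,
                  sqrt_spectrum = sqrt_spectrum)
  exp(env$mu0 + g)
}

#' Poisson reproduction of semelparous adults
#'
#' Each individual produces a Poisson-distributed number of propagules with
#' mean equal to the fecundity of its own cell (reproduction precedes
#' dispersal), then dies.  Propagules start at the parent position.
#'
#' @param pop a [population()].
#' @param mu L x L fecundity matrix (see [sample_fecundity_field()]).
#' @return P x 2 matrix of propagule positions (one row per propagule).
#' @export
reproduce <- function(pop, mu) {
  stopifnot(inherits(pop, "population"))
  n <- nrow(pop$xy)
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  counts <- stats::rpois(n, mu[cell_linear(pop$xy, pop$L)])
  pop$xy[rep.int(seq_len(n), counts), , drop = FALSE]
}

#' Gaussian dispersal on the torus
#'
#' Each propagule is displaced by independent Normal(0, alpha_d^2) draws per
#' axis, wrapped modulo `L`.  `alpha_d = Inf` disperses uniformly over the
#' landscape (mass-action mixing).
#'
#' @param xy P x 2 matrix of positions.
#' @param alpha_d dispersal scale (> 0 or `Inf`).
#' @param L lattice side length.
#' @return P x 2 matrix of wrapped post-dispersal positions.
#' @export
disperse <- function(xy, alpha_d, L) {
  check_scale(alpha_d, "alpha_d")
  p <- nrow(xy)
  if (p == 0L) return(xy)
  if (is.infinite(alpha_d))
    return(cbind(stats::runif(p, 0, L), stats::runif(p, 0, L)))
  wrap_torus(xy + matrix(stats::rnorm(2L * p, 0, alpha_d), ncol = 2L), L)
}

#' Remove propagules that landed in the matrix
#'
#' Propagules whose containing cell is not habitat die immediately and do
#' not influence competition.
#'
#' @param xy P x 2 matrix of positions.
#' @param land a [landscape()].
#' @return matrix of surviving positions.
#' @export
filter_matrix <- function(xy, land) {
  stopifnot(inherits(land, "landscape"))
  if (nrow(xy) == 0L) return(xy)
  xy[land$mask[cell_linear(xy, land$L)], , drop = FALSE]
}

# discretized bivariate Gaussian competition kernel at minimum-image lags,
# normalized to sum 1 so the convolved value is a density per unit cell area
competition_kernel <- function(L, alpha_c) {
  lag <- pmin(0:(L - 1L), L - (0:(L - 1L)))
  k <- exp(-outer(lag^2, lag^2, "+") / (2 * alpha_c^2))
  k / sum(k)
}

#' Local propagule density by kernel convolution
#'
#' Propagules are binned to cells; the cell counts are circularly convolved
#' (on the torus, via FFT) with a discretized bivariate Gaussian kernel of
#' scale `alpha_c` normalized to sum 1, and each propagule is assigned the
#' convolved value at its own cell — a propagule density per unit area.
#' `alpha_c = Inf` gives every propagule the global density
#' `P / L^2` (the uniform-kernel limit of the convolution).
#'
#' @param xy P x 2 matrix of (habitat-surviving) propagule positions.
#' @param alpha_c competition scale (> 0 or `Inf`).
#' @param land a [landscape()].
#' @param kernel_fft optional precomputed `fft(competition_kernel(L, alpha_c))`.
#' @return numeric vector of length P of local densities.
#' @export
local_density <- function(xy, alpha_c, land, kernel_fft = NULL) {
  check_scale(alpha_c, "alpha_c")
  L <- land$L
  p <- nrow(xy)
  if (p == 0L) return(numeric(0))
  if (is.infinite(alpha_c)) return(rep.int(p / (L * L), p))
  cells <- cell_linear(xy, L)
  counts <- matrix(tabulate(cells, nbins = L * L), L, L)
  if (is.null(kernel_fft))
    kernel_fft <- stats::fft(competition_kernel(L, alpha_c))
  dens <- Re(stats::fft(stats::fft(counts) * kernel_fft,
                        inverse = TRUE)) / (L * L)
  dens[cells]
}

#' Density-dependent establishment
#'
#' Each propagule independently becomes an adult of the next generation with
#' probability `1 / (1 + b * n_i)`, where `n_i` is its local propagule
#' density; survivors keep their landing positions.
#'
#' @param xy P x 2 matrix of propagule positions.
#' @param n numeric vector of local densities (length P).
#' @param b competition strength (>= 0).
#' @return matrix of established positions.
#' @export
establish <- function(xy, n, b) {
  stopifnot(b >= 0, nrow(xy) == length(n))
  if (nrow(xy) == 0L) return(xy)
  xy[stats::runif(length(n)) < 1 / (1 + b * n), , drop = FALSE]
}

#' Precompute reusable FFTs for a simulation
#'
#' Builds the competition-kernel FFT and the regional-stochasticity
#' square-root spectrum once, so repeated [step_generation()] calls avoid
#' redundant transforms.
#'
#' @param land a [landscape()].
#' @param species a [species_params()].
#' @param env an [env_params()].
#' @return list of class `"sim_plan"`.
#' @export
make_sim_plan <- function(land, species, env) {
  stopifnot(inherits(land, "landscape"), inherits(species, "species_params"),
            inherits(env, "env_params"))
  L <- land$L
  kernel_fft <- if (is.finite(species$alpha_c))
    stats::fft(competition_kernel(L, species$alpha_c)) else NULL
  env_sqrt_spec <- if (env$sigma_r2 > 0 && is.finite(env$alpha_r))
    sqrt(spectral_density(L, env$alpha_r, env$sigma_r2)) else NULL
  structure(list(kernel_fft = kernel_fft, env_sqrt_spec = env_sqrt_spec),
            class = "sim_plan")
}

#' Advance the population by one generation
#'
#' Applies, in order: fecundity-field resampling, Poisson reproduction,
#' Gaussian dispersal, matrix mortality, kernel-convolved local density,
#' and Bernoulli establishment.  An empty population is absorbing.  The
#' returned population carries the attribute `mu_mean`, the spatial mean of
#' this generation's fecundity field (for `alpha_r = Inf` this is exactly
#' the shared global fecundity draw), used by mean-field comparators.
#'
#' @param pop a [population()].
#' @param land a [landscape()].
#' @param species a [species_params()].
#' @param env an [env_params()].
#' @param plan optional [make_sim_plan()] result.
#' @return a [population()] (next generation) with attribute `mu_mean`.
#' @export
step_generation <- function(pop, land, species, env, plan = NULL) {
  stopifnot(inherits(pop, "population"), pop$L == land$L)
  if (is.null(plan)) plan <- make_sim_plan(land, species, env)
  L <- land$L
  if (nrow(pop$xy) == 0L) {
    out <- population(matrix(numeric(0), ncol = 2L), L)
    attr(out, "mu_mean") <- NA_real_
    return(out)
  }
  # fecundity resampled even for an occupied landscape corner: one global
  # draw when alpha_r = Inf, otherwise a full field
  if (env$sigma_r2 == 0) {
    mu_scalar <- exp(env$mu0)
    mu <- NULL
  } else if (is.infinite(env$alpha_r)) {
    mu_scalar <- exp(env$mu0 + stats::rnorm(1L, 0, sqrt(env$sigma_r2)))
    mu <- NULL
  } else {
    mu <- sample_fecundity_field(env, L, sqrt_spectrum = plan$env_sqrt_spec)
    mu_scalar <- NA_real_
  }
  n_adults <- nrow(pop$xy)
  if (is.null(mu)) {
    counts <- stats::rpois(n_adults, mu_scalar)
    props <- pop$xy[rep.int(seq_len(n_adults), counts), , drop = FALSE]
    mu_mean <- mu_scalar
  } else {
    counts <- stats::rpois(n_adults, mu[cell_linear(pop$xy, L)])
    props <- pop$xy[rep.int(seq_len(n_adults), counts), , drop = FALSE]
    mu_mean <- mean(mu)
  }
  props <- disperse(props, species$alpha_d, L)
  props <- filter_matrix(props, land)
  if (nrow(props) > 0L) {
    dens <- local_density(props, species$alpha_c, land,
                          kernel_fft = plan$kernel_fft)
    props <- establish(props, dens, species$b)
  }
  out <- population(props, L)
  attr(out, "mu_mean") <- mu_mean
  out
}

#' One step of the (stochastic) Beverton-Holt mean-field model
#'
#' The mass-action comparator for the individual-based model:
#' `N' = N * mu * h / (1 + b * N * mu * h)`, where `N` is global population
#' density per unit landscape area, `mu` the realized fecundity of the
#' generation, and `h` the habitat cover.  In the stochastic version
#' `log(mu)` is drawn Normal(mu0, sigma_r2) each step.
#'
#' @param N global population density (>= 0).
#' @param mu realized fecundity of the generation (> 0).
#' @param h proportional habitat cover in `[0, 1]`.
#' @param b competition strength (>= 0).
#' @return next-generation density.
#' @export
#' @examples
#' # positive fixed point (mu*h - 1) / (b*mu*h):
#' mean_field_step(0.4545455, 1.1, 1, 0.2)
mean_field_step <- function(N, mu, h, b) {
  stopifnot(all(N >= 0), all(mu >= 0), h >= 0, h <= 1, b >= 0)
  N * mu * h / (1 + b * N * mu * h)
}

#' Iterate the mean-field map along a fecundity sequence
#'
#' @param N0 initial density.
#' @param mu_seq vector of realized per-generation fecundities.
#' @inheritParams mean_field_step
#' @return density trajectory of length `length(mu_seq)` (excluding `N0`).
#' @export
mean_field_trajectory <- function(N0, mu_seq, h, b) {
  N <- numeric(length(mu_seq))
  cur <- N0
  for (t in seq_along(mu_seq)) {
    cur <- mean_field_step(cur, mu_seq[t], h, b)
    N[t] <- cur
  }
  N
}
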