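# Experiment drivers: persistence, abundance, synchrony, calibration.
# All drivers expand one top-level seed into per-replicate child seeds
# (child_seed), so any replicate is reproducible in isolation.

run_one_replicate <- function(land, species, env, plan, init_density, t_max,
                              record = FALSE) {
  pop <- init_population(land, init_density)
  n_series <- if (record) integer(t_max) else NULL
  mu_series <- if (record) rep(NA_real_, t_max) else NULL
  ext_time <- NA_integer_
  for (t in seq_len(t_max)) {
    pop <- step_generation(pop, land, species, env, plan)
    if (record) {
      n_series[t] <- nrow(pop$xy)
      mu_series[t] <- attr(pop, "mu_mean")
    }
    if (nrow(pop$xy) == 0L) { ext_time <- t; break }
  }
  list(pop = pop, extinction = ext_time, N = n_series, mu = mu_series)
}

#' Mean time to global extinction by Monte Carlo
#'
#' Runs `reps` independent replicates, each freshly initialized with
#' `init_density` spatially randomized individuals per unit area, until no
#' individual remains or `t_max` generations have elapsed.  Replicates that
#' reach `t_max` are censored and enter the mean at `t_max`; the censored
#' fraction is always reported alongside.
#'
#' @param land a [landscape()].
#' @param species a [species_params()].
#' @param env an [env_params()]; the headline persistence analysis uses
#'   globally synchronized stochasticity (`alpha_r = Inf`).
#' @param reps number of replicates (>= 1).
#' @param t_max terminal generation (cap), default 5e5.
#' @param init_density initial individuals per unit landscape area
#'   (default `1000/3600`).
#' @param seed top-level seed.
#' @return object of class `"persistence_result"`: a list with `times`
#'   (data.frame: replicate, time, censored), `mean_time`, `censored_frac`,
#'   and the configuration.
#' @export
run_persistence <- function(land, species, env, reps, t_max = 5e5,
                            init_density = 1000 / 3600, seed = 1L) {
  stopifnot(reps >= 1, t_max >= 1)
  plan <- make_sim_plan(land, species, env)
  times <- integer(reps)
  cens <- logical(reps)
  for (k in seq_len(reps)) {
    set.seed(child_seed(seed, k))
    r <- run_one_replicate(land, species, env, plan, init_density, t_max)
    if (is.na(r$extinction)) {
      times[k] <- t_max
      cens[k] <- TRUE
    } else {
      times[k] <- r$extinction
    }
  }
  structure(list(
    times = data.frame(replicate = seq_len(reps), time = times,
                       censored = cens),
    mean_time = mean(times),
    censored_frac = mean(cens),
    config = list(reps = reps, t_max = t_max, init_density = init_density,
                  seed = seed, species = unclass(species),
                  env = unclass(env), landscape = land$provenance)),
    class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf(
    "<persistence_result> %d replicates: mean time %.1f generations (%.0f%% censored at %g)\n",
    nrow(x$times), x$mean_time, 100 * x$censored_frac, x$config$t_max))
  invisible(x)
}

#' Paired persistence with and without habitat aggregation
#'
#' Runs [run_persistence()] on the landscape as given and on its
#' [aggregate_habitat()] transform (same total habitat, one compact patch),
#' with paired replicate seeds, to isolate the effect of habitat
#' configuration alone (fragmentation per se).
#'
#' @inheritParams run_persistence
#' @return list of class `"aggregation_result"` with `original`,
#'   `aggregated` (both [run_persistence()] results) and `ratio`
#'   (aggregated mean over original mean).
#' @export
run_persistence_aggregated <- function(land, species, env, reps, t_max = 5e5,
                                       init_density = 1000 / 3600, seed = 1L) {
  orig <- run_persistence(land, species, env, reps, t_max, init_density, seed)
  aggl <- aggregate_habitat(land)
  aggr <- run_persistence(aggl, species, env, reps, t_max, init_density, seed)
  structure(list(original = orig, aggregated = aggr,
                 ratio = aggr$mean_time / orig$mean_time),
            class = "aggregation_result")
}

#' Abundance trajectories with a stochastic mean-field comparator
#'
#' Tracks global population size for `generations` generations in each of
#' `reps` replicates, and computes, per replicate, the stochastic
#' Beverton-Holt mean-field trajectory (same `h`, `b`) driven by the
#' realized per-generation mean fecundities of that replicate, so the two
#' series are directly comparable (for `alpha_r = Inf` the realized mean is
#' exactly the shared global fecundity draw).
#'
#' @inheritParams run_persistence
#' @param generations number of generations to track (quasistationarity is
#'   conventionally assessed on the final 50).
#' @param init_density initial individuals per unit area (default
#'   `5000 / land$L^2` is *not* assumed; pass explicitly).
#' @return object of class `"abundance_series"`: list with `N`
#'   (reps x generations integer matrix of population sizes), `mu`
#'   (realized mean fecundities), `meanfield` (reps x generations matrix of
#'   mean-field population sizes, density times `L^2`), `h`, and config.
#' @export
run_abundance <- function(land, species, env, reps, generations,
                          init_density = 1000 / 3600, seed = 1L) {
  stopifnot(reps >= 1, generations >= 1)
  plan <- make_sim_plan(land, species, env)
  L <- land$L
  h <- habitat_cover(land)
  N <- matrix(0L, reps, generations)
  MU <- matrix(NA_real_, reps, generations)
  MF <- matrix(0, reps, generations)
  n0 <- round(init_density * L * L)
  for (k in seq_len(reps)) {
    set.seed(child_seed(seed, k))
    r <- run_one_replicate(land, species, env, plan, init_density,
                           generations, record = TRUE)
    N[k, ] <- r$N
    MU[k, ] <- r$mu
    # drive the mean-field map with the same realized fecundities; after
    # simulated extinction mu is undrawn, so extend with fresh draws
    mu_seq <- r$mu
    nd <- which(is.na(mu_seq))
    if (length(nd))
      mu_seq[nd] <- exp(env$mu0 + stats::rnorm(length(nd), 0,
                                               sqrt(env$sigma_r2)))
    MF[k, ] <- mean_field_trajectory(n0 / (L * L), mu_seq, h, species$b) *
      (L * L)
  }
  structure(list(N = N, mu = MU, meanfield = MF, h = h,
                 config = list(reps = reps, generations = generations,
                               init_density = init_density, seed = seed,
                               species = unclass(species),
                               env = unclass(env),
                               landscape = land$provenance)),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  g <- ncol(x$N)
  last <- max(1L, g - 49L):g
  cat(sprintf(
    "<abundance_series> %d replicates x %d generations; mean N (last %d) = %.1f, mean-field %.1f\n",
    nrow(x$N), g, length(last), mean(x$N[, last]), mean(x$meanfield[, last])))
  invisible(x)
}

#' Calibrate mean log-fecundity to a target global population size
#'
#' Adjusts `mu0` so that the mean population size at generation
#' `generations`, over a pilot ensemble, falls within
#' `target_n` plus/minus `band`.  The search is a bracketed bisection on
#' `mu0` (achieved size is increasing in `mu0` over the viable range), run
#' with common random numbers across evaluations; the initial guess inverts
#' the mean-field fixed point `N* = (mu*h - 1) / (b*mu*h)` for `mu`.
#'
#' @inheritParams run_persistence
#' @param target_n target mean global population size (individuals).
#' @param band half-width of the acceptance band around `target_n`.
#' @param pilot_reps pilot ensemble size per evaluation (default 100).
#' @param generations pilot run length (default 50).
#' @param init_density initial density per unit area (default
#'   `5000 / land$L^2`).
#' @param mu0_range numeric length-2 search range for `mu0`.
#' @param max_iter maximum bisection iterations.
#' @return the calibrated `mu0`, with attributes `achieved_n` (pilot mean at
#'   the returned value) and `evaluations` (data.frame of the search path).
#' @export
calibrate_mu0 <- function(land, species, env, target_n = 1000, band = 200,
                          pilot_reps = 100, generations = 50,
                          init_density = NULL, seed = 1L,
                          mu0_range = c(-5, 8), max_iter = 30) {
  stopifnot(band > 0, pilot_reps >= 1)
  if (is.null(init_density)) init_density <- 5000 / land$L^2
  h <- habitat_cover(land)
  if (h == 0) stop("cannot calibrate on a landscape without habitat")
  evals <- list()
  pilot <- function(mu0) {
    e <- env_params(mu0 = mu0, sigma_r2 = env$sigma_r2, alpha_r = env$alpha_r)
    ab <- run_abundance(land, species, e, reps = pilot_reps,
                        generations = generations,
                        init_density = init_density, seed = seed)
    m <- mean(ab$N[, generations])
    evals[[length(evals) + 1L]] <<- data.frame(mu0 = mu0, mean_n = m)
    m
  }
  # mean-field inversion for the initial guess: N* = (mu*h-1)/(b*mu*h)
  nstar <- target_n / land$L^2
  guess <- if (species$b * nstar < 1)
    log(1 / (h * (1 - species$b * nstar))) else env$mu0
  guess <- min(max(guess, mu0_range[1L]), mu0_range[2L])
  m <- pilot(guess)
  if (abs(m - target_n) <= band)
    return(structure(guess, achieved_n = m,
                     evaluations = do.call(rbind, evals)))
  # expand a bracket around the guess
  step <- 0.5
  lo <- hi <- guess; m_lo <- m_hi <- m
  while (m_lo > target_n && lo > mu0_range[1L]) {
    lo <- max(lo - step, mu0_range[1L]); m_lo <- pilot(lo)
  }
  while (m_hi < target_n && hi < mu0_range[2L]) {
    hi <- min(hi + step, mu0_range[2L]); m_hi <- pilot(hi)
  }
  if (m_lo > target_n || m_hi < target_n)
    stop(sprintf(
      "calibration failed to bracket target %g in mu0 range [%g, %g]; achieved [%g, %g]",
      target_n, mu0_range[1L], mu0_range[2L], m_lo, m_hi))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    m <- pilot(mid)
    if (abs(m - target_n) <= band)
      return(structure(mid, achieved_n = m,
                       evaluations = do.call(rbind, evals)))
    if (m < target_n) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration did not converge within %d bisections; last mean N = %.1f (target %g +/- %g)",
    max_iter, m, target_n, band))
}
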