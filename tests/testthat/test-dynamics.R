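test_that("fecundity field honours the noise-free and global-noise limits", {
  env0 <- env_params(mu0 = log(1.1), sigma_r2 = 0)
  expect_true(all(sample_fecundity_field(env0, 8) == 1.1))

  # alpha_r = Inf: one shared draw per generation, log-values N(mu0, s2)
  env <- env_params(mu0 = log(1.1), sigma_r2 = 0.5, alpha_r = Inf)
  set.seed(30)
  draws <- replicate(2000, {
    f <- sample_fecundity_field(env, 6)
    expect_equal(length(unique(as.vector(f))), 1L)
    log(f[1, 1])
  })
  expect_lt(abs(mean(draws) - log(1.1)), 3 * sd(draws) / sqrt(2000))
  expect_equal(var(draws), 0.5, tolerance = 0.1)
})

test_that("fecundity field has the stated spatial log-covariance", {
  env <- env_params(mu0 = 0, sigma_r2 = 0.5, alpha_r = 1.5)
  set.seed(31)
  L <- 24
  ss <- sqrt(spectral_density(L, 1.5, 0.5))
  # covariance of log-fecundity at distance 1.5 (average lags d=1 and d=2
  # bracket it; use lag 1 and the interpolating target at d = 1)
  acc1 <- 0
  nrep <- 1500
  for (k in seq_len(nrep)) {
    g <- log(sample_fecundity_field(env, L, sqrt_spectrum = ss))
    acc1 <- acc1 + mean((g - 0) * (g[c(2:L, 1), ] - 0))
  }
  expect_lt(abs(acc1 / nrep - 0.5 * exp(-1 / 1.5)), 0.05)
})

test_that("reproduction is Poisson with the parent-cell fecundity", {
  land <- make_homogeneous(10)
  empty <- population(matrix(numeric(0), ncol = 2), 10)
  expect_equal(nrow(reproduce(empty, matrix(1.1, 10, 10))), 0L)

  set.seed(32)
  pop <- init_population(land, density = 1000)  # 100,000 on the 10 x 10 grid
  props <- reproduce(pop, matrix(1.1, 10, 10))
  n <- pop_size(pop)
  se <- sqrt(1.1 / n)   # Poisson mean SE
  expect_lt(abs(nrow(props) / n - 1.1), 3 * se)
  # vanishing fecundity: almost surely no propagules
  expect_equal(nrow(reproduce(pop, matrix(1e-12, 10, 10))), 0L)
})

test_that("dispersal has the right kernel in each regime", {
  set.seed(33)
  parents <- matrix(30, 1e5, 2)
  moved <- disperse(parents, alpha_d = 2, L = 60)
  # unwrap via minimum image (alpha_d << L so wrapping is unambiguous)
  disp <- (moved - parents + 30) %% 60 - 30
  expect_equal(var(disp[, 1]), 4, tolerance = 0.02)
  expect_equal(var(disp[, 2]), 4, tolerance = 0.02)
  expect_lt(abs(cor(disp[, 1], disp[, 2])), 0.02)

  # alpha_d -> 0: offspring stay at the parent position
  still <- disperse(parents[1:100, ], alpha_d = 1e-12, L = 60)
  expect_equal(still, parents[1:100, ], tolerance = 1e-9)

  # alpha_d = Inf: uniform cell occupancy (chi-square at the 1% level)
  set.seed(34)
  unif <- disperse(parents, alpha_d = Inf, L = 60)
  counts <- tabulate(fragmeta:::cell_linear(unif, 60), nbins = 3600)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("matrix mortality keeps exactly the propagules on habitat", {
  set.seed(35)
  land <- make_fragmented(20, 3, 0.5)
  xy <- cbind(runif(5000, 0, 20), runif(5000, 0, 20))
  kept <- filter_matrix(xy, land)
  # brute-force per-propagule lookup oracle
  onhab <- vapply(seq_len(nrow(xy)), function(i)
    land$mask[floor(xy[i, 1]) + 1, floor(xy[i, 2]) + 1], logical(1))
  expect_equal(nrow(kept), sum(onhab))
  expect_equal(kept, xy[onhab, , drop = FALSE])
  # limit landscapes
  expect_equal(nrow(filter_matrix(xy, make_homogeneous(20))), nrow(xy))
  nohab <- landscape(matrix(FALSE, 20, 20))
  expect_equal(nrow(filter_matrix(xy, nohab)), 0L)
})

test_that("local density convolution matches direct pairwise summation", {
  land <- make_homogeneous(16)
  # a single propagule sees only the kernel weight at lag 0
  one <- matrix(c(4.2, 9.7), 1, 2)
  k <- fragmeta:::competition_kernel(16, 2)
  expect_equal(local_density(one, 2, land), k[1, 1])
  # uniform one-propagule-per-cell input: density 1 everywhere
  grid_xy <- as.matrix(expand.grid(x = 0:15 + 0.5, y = 0:15 + 0.5))
  expect_equal(local_density(grid_xy, 2, land), rep(1, 256))
  # FFT convolution vs direct O(P^2) sum on random inputs
  set.seed(36)
  for (alpha_c in c(0.8, 2)) {
    xy <- cbind(runif(300, 0, 16), runif(300, 0, 16))
    expect_equal(local_density(xy, alpha_c, land),
                 brute_force_density(xy, alpha_c, 16), tolerance = 1e-10)
  }
  # global competition: everyone sees P / L^2
  expect_equal(local_density(grid_xy, Inf, land), rep(256 / 256, 256))
})

test_that("establishment is Bernoulli with probability 1/(1 + b n)", {
  xy <- matrix(runif(2e4, 0, 10), ncol = 2)
  # zero density: certain establishment
  expect_equal(establish(xy, rep(0, nrow(xy)), b = 0.2), xy)
  # b = 0.2, n = 5 => e = 0.5
  set.seed(37)
  surv <- replicate(50, nrow(establish(xy, rep(5, nrow(xy)), b = 0.2)))
  p <- mean(surv) / nrow(xy)
  se <- sqrt(0.5 * 0.5 / (nrow(xy) * 50))
  expect_lt(abs(p - 0.5), 3 * se)
  # heterogeneous densities: expected survivors = sum of e_i
  set.seed(38)
  n <- runif(nrow(xy), 0, 10)
  e <- 1 / (1 + 0.2 * n)
  surv <- replicate(100, nrow(establish(xy, n, b = 0.2)))
  se <- sqrt(sum(e * (1 - e)) / 100)
  expect_lt(abs(mean(surv) - sum(e)), 3 * se)
})

test_that("a generation step composes the stages and absorbs extinction", {
  land <- make_homogeneous(20)
  sp <- species_params(alpha_d = 1, b = 0.2)
  env <- env_params(mu0 = log(1.1), sigma_r2 = 0.5, alpha_r = Inf)
  # empty population is absorbing
  empty <- population(matrix(numeric(0), ncol = 2), 20)
  expect_equal(pop_size(step_generation(empty, land, sp, env)), 0L)
  # identical seed => bit-identical next generation
  pop <- local({set.seed(39); init_population(land, 0.5)})
  set.seed(40); g1 <- step_generation(pop, land, sp, env)
  set.seed(40); g2 <- step_generation(pop, land, sp, env)
  expect_identical(g1$xy, g2$xy)
  # all offspring are on habitat cells
  set.seed(41)
  landf <- make_fragmented(20, 3, 0.5)
  popf <- init_population(landf, 0.5)
  for (i in 1:5) {
    popf <- step_generation(popf, landf, sp, env)
    if (pop_size(popf) == 0) break
    expect_true(all(landf$mask[fragmeta:::cell_linear(popf$xy, 20)]))
  }
})

test_that("without competition the step is a branching process in the mean", {
  land <- make_homogeneous(30)
  sp <- species_params(alpha_d = 2, b = 0)
  env <- env_params(mu0 = log(1.1), sigma_r2 = 0)
  set.seed(42)
  pop <- init_population(land, 2)       # 1800 individuals
  n0 <- pop_size(pop)
  next_n <- replicate(200, pop_size(step_generation(pop, land, sp, env)))
  se <- sqrt(n0 * 1.1 / 200)            # Poisson total per replicate
  expect_lt(abs(mean(next_n) - n0 * exp(log(1.1))), 3 * se)
})

test_that("initial populations have the printed counts and live on habitat", {
  set.seed(43)
  pop <- init_population(make_homogeneous(60), 1000 / 3600)
  expect_equal(pop_size(pop), 1000L)
  pop5 <- init_population(make_homogeneous(60), 5000 / 3600)
  expect_equal(pop_size(pop5), 5000L)
  expect_equal(pop_size(init_population(make_homogeneous(10), 0)), 0L)
  # fragmented landscape: all individuals on habitat
  land <- make_fragmented(30, 3, 0.5)
  pop <- init_population(land, 1)
  expect_true(all(land$mask[fragmeta:::cell_linear(pop$xy, 30)]))
  # zero-habitat landscape: empty population with a warning
  nohab <- landscape(matrix(FALSE, 10, 10))
  expect_warning(p0 <- init_population(nohab, 1), "no habitat")
  expect_equal(pop_size(p0), 0L)
})

test_that("mean-field map has the documented fixed points", {
  expect_equal(mean_field_step(0, 1.1, 1, 0.2), 0)
  # positive fixed point (mu h - 1) / (b mu h)
  nstar <- (1.1 - 1) / (0.2 * 1.1)
  expect_equal(mean_field_step(nstar, 1.1, 1, 0.2), nstar)
  expect_equal(nstar, 0.4545455, tolerance = 1e-6)
  # subcritical growth (mu h <= 1): iterates decrease monotonically to 0
  traj <- mean_field_trajectory(0.5, rep(0.9, 200), h = 1, b = 0.2)
  expect_true(all(diff(traj) < 0))
  expect_lt(traj[200], 1e-3)
  traj2 <- mean_field_trajectory(0.5, rep(2, 100), h = 0.5, b = 0.2)
  expect_true(all(diff(c(0.5, traj2)) <= 0))  # mu h = 1: nonincreasing
})
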