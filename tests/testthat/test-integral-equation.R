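# The Volterra route: free density, kernel, and the discretized solver.

test_that("free density reduces to the exponential form for n = 2 from the origin", {
  y <- seq(0, 10, by = 0.25)
  t <- 0.8
  expect_equal(free_density(y, t, y0 = 0, tau = 0, n = 2),
               exp(-y / (2 * t)) / (2 * t), tolerance = 1e-12)
})

test_that("free density integrates to one", {
  set.seed(7)
  for (n in c(2, 3, 4)) {
    y0 <- stats::runif(1, 0, 4)
    t <- stats::runif(1, 0.2, 2)
    mass <- stats::integrate(function(y) free_density(y, t, y0, 0, n),
                             0, Inf, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
})

test_that("free density satisfies Chapman-Kolmogorov", {
  n <- 3; y0 <- 1.3; tau <- 0; s <- 0.6; t <- 1.4; y <- 2.1
  conv <- stats::integrate(function(z)
    free_density(y, t, z, s, n) * free_density(z, s, y0, tau, n),
    0, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
  expect_equal(conv, free_density(y, t, y0, tau, n), tolerance = 1e-6)
})

test_that("kernel vanishes along the boundary as tau -> t and is finite elsewhere", {
  th <- threshold_constant(1.5)
  t <- 1
  lags <- c(1e-1, 1e-2, 1e-3, 1e-4)
  psi <- abs(kernel_psi(t, t - lags, th$S(t - lags), 2, th))
  expect_true(all(diff(psi) < 0))
  expect_lt(psi[length(psi)], 1e-4)
  # same property with a collapsing boundary
  thc <- threshold_linear(3, 1.5)
  psi_c <- abs(kernel_psi(1, 1 - lags, thc$S(1 - lags), 2, thc))
  expect_true(all(diff(psi_c) < 0))
  expect_true(all(is.finite(kernel_psi(0.5, c(0, 0.1), c(0, 0.3), 4, th))))
  expect_error(kernel_psi(2.5, 1, 1, 2, thc), "singular")
})

test_that("constant-threshold first-step values give a nonnegative density start", {
  for (dt in c(0.005, 0.01, 0.02)) {
    th <- threshold_constant(2)
    expect_gte(-2 * kernel_psi(dt, 0, 0, 2, th), 0)
  }
})

test_that("integral-equation density matches the Bessel-series oracle", {
  # constant thresholds, all tested dimensions and radii; comparison region
  # starts past the series' short-time instability (scales with b^2)
  worst <- 0
  for (n in c(2, 3, 4)) for (b in c(1, 2, 5)) {
    grid <- solve_fpt(n, threshold_constant(b), delta_t = 0.01)
    lo <- 0.075 * b^2
    idx <- grid$times >= lo
    err <- max(abs(grid$g[idx] -
                     series_fpt_density(grid$times[idx], b, n, k_terms = 500)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-3)
})

test_that("grid mass is one when the horizon covers the distribution", {
  for (n in c(2, 3)) {
    grid <- solve_fpt(n, threshold_constant(1.5), delta_t = 0.01)
    mass <- hsdmie:::grid_mass(grid)
    expect_gte(mass, 0.99)
    expect_lte(mass, 1.005)
    expect_gt(min(grid$g), -1e-4)
  }
})

test_that("rectangle scheme converges with delta_t at first order or better", {
  # halving the step drives the node error against the series oracle down
  # monotonically (n = 3) ...
  errs3 <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    grid <- solve_fpt(3, threshold_constant(1), delta_t = dt, t_max = 2.5)
    idx <- grid$times >= 0.3
    max(abs(grid$g[idx] - series_fpt_density(grid$times[idx], 1, 3)))
  }, numeric(1))
  expect_true(all(diff(errs3) < 0))
  # ... and the log-log slope is at least the scheme's first order (n = 2;
  # half-integer Bessel orders converge much faster still)
  dts <- c(0.1, 0.05, 0.025, 0.0125)
  errs2 <- vapply(dts, function(dt) {
    grid <- solve_fpt(2, threshold_constant(1), delta_t = dt, t_max = 2.5)
    idx <- grid$times >= 0.3
    max(abs(grid$g[idx] - series_fpt_density(grid$times[idx], 1, 2)))
  }, numeric(1))
  expect_true(all(diff(errs2) < 0))
  slope <- unname(coef(stats::lm(log(errs2) ~ log(dts)))[2])
  expect_gt(slope, 0.8)
})

test_that("collapsing-threshold grid matches simulated zero-drift passages", {
  grid <- solve_fpt(2, threshold_linear(3, 1.5), delta_t = 0.01)
  expect_lt(grid$t_max, 2)  # truncated below the singular time b0/lambda = 2
  p <- hsdm_params(2, c(0, 0), 0, threshold_linear(3, 1.5))
  # fine simulation step: the Euler overshoot shifts the boundary by about
  # 0.6 * sqrt(dt_sim), which must stay well inside the tolerance
  sim <- simulate_trials(p, 1e5, dt_sim = 2.5e-4, seed = 31)
  ks <- ks_distance(sim$rt, grid$times, trap_cdf(grid$g, grid$delta_t))
  expect_lt(ks, 0.01)
})

test_that("grid evaluation interpolates linearly and is zero outside support", {
  grid <- solve_fpt(2, threshold_constant(1), delta_t = 0.05, t_max = 2)
  i <- 10
  expect_identical(density_at(grid, grid$times[i]), grid$g[i])
  mid <- (grid$times[i] + grid$times[i + 1]) / 2
  expect_equal(density_at(grid, mid), (grid$g[i] + grid$g[i + 1]) / 2)
  expect_identical(density_at(grid, -0.1), 0)
  expect_identical(density_at(grid, 0), 0)
  expect_identical(density_at(grid, grid$t_max + 1), 0)
  # below the first node: ramp from g(0) = 0
  expect_equal(density_at(grid, 0.025), grid$g[1] / 2)
})

test_that("horizon requests crossing the singular time are refused clearly", {
  expect_error(solve_fpt(2, threshold_linear(1, 2), delta_t = 0.4),
               "singular")
})
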