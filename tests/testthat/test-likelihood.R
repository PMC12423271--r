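# Girsanov joint density and trial-set likelihood.

test_that("zero drift gives a uniform angular density g(T)/A", {
  p <- hsdm_params(2, c(0, 0), 0.2, threshold_constant(1.5))
  grid <- solve_fpt(2, threshold_constant(1.5), 0.01)
  rt <- c(0.6, 1.1, 2)
  for (ph in c(0, 1, pi, 5)) {
    expect_equal(joint_density(rt, matrix(ph, 3, 1), p, grid),
                 density_at(grid, rt - 0.2) / (2 * pi), tolerance = 1e-12)
  }
})

test_that("the change-of-measure wrapper is algebraically exact given g", {
  # same g input on both routes: solver grid vs series density, wrapped by
  # hand with the exponential factor
  p <- hsdm_params(2, c(2, -1), 0.1, threshold_constant(2))
  grid <- solve_fpt(2, threshold_constant(2), 0.01)
  rt <- c(0.4, 0.9, 1.7)
  phi <- c(0.3, 2.0, 5.5)
  jd <- joint_density(rt, matrix(phi, ncol = 1), p, grid)
  tt <- rt - 0.1
  x <- 2 * cbind(cos(phi), sin(phi))
  by_hand <- exp(x %*% c(2, -1) - 0.5 * 5 * tt) * density_at(grid, tt) / (2 * pi)
  expect_equal(jd, as.numeric(by_hand), tolerance = 1e-10)
})

test_that("responses aligned with drift are likelier than opposed ones", {
  p <- hsdm_params(2, c(2, 2), 0.2, threshold_constant(2))
  phi_mu <- atan2(2, 2)
  aligned <- joint_density(1, phi_mu, p, delta_t = 0.01)
  opposed <- joint_density(1, (phi_mu + pi) %% (2 * pi), p, delta_t = 0.01)
  expect_gt(aligned, opposed)
})

test_that("joint density integrates to one over time and angle (n = 2)", {
  p <- hsdm_params(2, c(1.5, 1), 0, threshold_constant(2))
  grid <- solve_fpt(2, threshold_constant(2), 0.01)
  phis <- seq(0, 2 * pi, length.out = 181)[-181]
  tot <- 0
  for (ph in phis) {
    jd <- joint_density(grid$times, matrix(ph, length(grid$times), 1), p,
                        grid)
    tot <- tot + sum(jd) * grid$delta_t * (2 * pi / 180)
  }
  expect_equal(tot, 1, tolerance = 1e-2)
})

test_that("likelihood is invariant to a joint rotation of drift and responses", {
  p <- hsdm_params(2, c(2, 1), 0.25, threshold_constant(2))
  set.seed(5)
  trials <- simulate_trials(p, 200, seed = 5)
  alpha <- 0.9
  rot <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2)
  p_rot <- hsdm_params(2, as.numeric(rot %*% c(2, 1)), 0.25, threshold_constant(2))
  trials_rot <- trials
  trials_rot$phi_1 <- (trials$phi_1 + alpha) %% (2 * pi)
  expect_equal(neg_log_likelihood(trials, p, 0.02),
               neg_log_likelihood(trials_rot, p_rot, 0.02), tolerance = 1e-9)
})

test_that("collapsing thresholds use b(T) at the stopping time in the exponent", {
  th <- threshold_linear(3, 1.5)
  p <- hsdm_params(2, c(1, 0), 0, th)
  grid <- solve_fpt(2, th, 0.01)
  rt <- 1.5   # b(1.5) = 0.75, much smaller than b(0) = 3
  jd <- joint_density(rt, 0, p, grid)
  by_hand <- exp(th$b(rt) * 1 - 0.5 * rt) * density_at(grid, rt) / (2 * pi)
  expect_equal(jd, by_hand, tolerance = 1e-12)
})

test_that("NLL prefers the generating threshold at large N", {
  p <- hsdm_params(2, c(2, 1), 0.3, threshold_constant(2))
  trials <- simulate_trials(p, 1000, seed = 17)
  nll_true <- neg_log_likelihood(trials, p, 0.02)
  for (fac in c(0.8, 1.2)) {
    p_alt <- hsdm_params(2, c(2, 1), 0.3, threshold_constant(2 * fac))
    expect_lt(nll_true, neg_log_likelihood(trials, p_alt, 0.02))
  }
})

test_that("floor rule keeps the objective finite for out-of-support trials", {
  p <- hsdm_params(2, c(1, 1), 0.5, threshold_constant(1))
  trials <- data.frame(rt = c(0.1, 0.2, 0.3), phi_1 = c(0, 1, 2))
  nll <- neg_log_likelihood(trials, p, 0.02)  # all rt < t0
  expect_equal(nll, -3 * log(1e-10))
})

test_that("dimension mismatches and malformed tables are rejected", {
  p3 <- hsdm_params(3, c(1, 0, 0), 0.2, threshold_constant(2))
  trials2 <- data.frame(rt = 1, phi_1 = 0.5)
  expect_error(neg_log_likelihood(trials2, p3, 0.02), "n = 3")
  expect_error(joint_density(1, c(0.5), p3), "angle")
  expect_error(hsdmie:::validate_trials(data.frame(rt = 1)), "phi_1")
  expect_error(hsdmie:::validate_trials(data.frame(rt = -1, phi_1 = 0)), "row")
  expect_error(hsdmie:::validate_trials(data.frame(rt = 1, phi_1 = 7)), "row")
})

test_that("trial CSVs round-trip losslessly through the readers", {
  p <- hsdm_params(3, c(1, 0, -1), 0.2, threshold_constant(2))
  trials <- simulate_trials(p, 50, seed = 9)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trials(trials, f)
  back <- read_trials(f)
  expect_equal(back$rt, trials$rt)
  expect_equal(back$phi_1, trials$phi_1)
  expect_equal(back$phi_2, trials$phi_2)
})
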