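test_that("precision index is b * ||mu|| / sigma^2 and needs a constant threshold", {
  p <- hsdm_params(2, c(6, 6), 0.3, threshold_constant(5))
  expect_equal(hsdm_kappa(p), 5 * sqrt(72), tolerance = 1e-12)
  expect_equal(hsdm_kappa(hsdm_params(2, c(0, 0), 0, threshold_constant(1))), 0)
  expect_equal(hsdm_kappa(hsdm_params(3, c(3, 0, 0), 0, threshold_constant(2),
                                      sigma = 2)), 1.5)
  p_col <- hsdm_params(2, c(1, 1), 0.3, threshold_linear(3, 1.5))
  expect_error(hsdm_kappa(p_col), "undefined")
})

test_that("linear threshold hits its endpoints and dS/dt matches -2*lambda*b(t)", {
  th <- threshold_linear(b0 = 3, lambda = 1.5)
  expect_equal(th$b(0), 3)
  expect_equal(th$t_singular, 2)
  expect_equal(th$b(th$t_singular), 0)
  tt <- c(0.1, 0.7, 1.4, 1.9)
  expect_equal(th$S(tt), th$b(tt)^2)
  expect_equal(th$dSdt(tt), -2 * 1.5 * (3 - 1.5 * tt))
  for (t in tt)
    expect_equal(th$dSdt(t), central_diff(th$S, t), tolerance = 1e-6)
})

test_that("custom thresholds derive S and dS/dt from b and db/dt", {
  th <- threshold_custom(function(t) 2 * exp(-0.3 * t),
                         function(t) -0.6 * exp(-0.3 * t))
  tt <- c(0, 0.5, 2)
  expect_equal(th$S(tt), (2 * exp(-0.3 * tt))^2)
  for (t in tt)
    expect_equal(th$dSdt(t), central_diff(th$S, t), tolerance = 1e-6)
})

test_that("spherical coordinates follow the nested sin/cos product", {
  expect_equal(spherical_to_cartesian(1, 0), c(1, 0))
  expect_equal(spherical_to_cartesian(2, c(pi / 2, 0)), c(0, 2, 0),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    x <- spherical_to_cartesian(1, random_angles(4))
    expect_equal(sqrt(sum(x^2)), 1, tolerance = 1e-12)
  }
  expect_error(spherical_to_cartesian(-1, 0), "positive")
})

test_that("cartesian/spherical round trip is exact on random points", {
  expect_equal(cartesian_to_spherical(c(0, -1))$phi, 3 * pi / 2)
  expect_equal(cartesian_to_spherical(c(3, 4))$radius, 5)
  expect_equal(cartesian_to_spherical(c(3, 4))$phi, atan2(4, 3))
  set.seed(42)
  worst <- 0
  for (n in 2:5) {
    for (i in 1:250) {
      x <- stats::rnorm(n)
      sp <- cartesian_to_spherical(x)
      back <- spherical_to_cartesian(sp$radius, sp$phi)
      worst <- max(worst, max(abs(back - x)))
      m <- length(sp$phi)
      if (m > 1) expect_true(all(sp$phi[-m] >= 0 & sp$phi[-m] <= pi))
      expect_true(sp$phi[m] >= 0 && sp$phi[m] < 2 * pi)
    }
  }
  expect_lt(worst, 1e-10)
  expect_error(cartesian_to_spherical(c(0, 0)), "zero")
})

test_that("sigma rescaling leaves the first-passage law of rt invariant", {
  # X -> X/sigma maps (mu, b, sigma) to (mu/sigma, b/sigma, 1) with the same
  # hitting times, so densities computed either way must agree
  p2 <- hsdm_params(2, c(2, 2), 0.2, threshold_constant(3), sigma = 2)
  p1 <- hsdm_params(2, c(1, 1), 0.2, threshold_constant(1.5), sigma = 1)
  rt <- c(0.5, 1, 2)
  expect_equal(marginal_rt_density(rt, p2, delta_t = 0.01),
               marginal_rt_density(rt, p1, delta_t = 0.01), tolerance = 1e-12)
})

test_that("model config JSON round-trips and rejects unknown keys", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(list(n = 3, mu = c(1, 2, -1), sigma = 1, t0 = 0.4,
                            threshold = list(kind = "linear", b0 = 4, lambda = 0.5)),
                       f, auto_unbox = TRUE)
  p <- parse_model_config(f)
  expect_equal(p$n, 3L)
  expect_equal(p$threshold$params$lambda, 0.5)
  expect_error(parse_model_config(list(n = 2, mu = c(1, 1), t0 = 0.1, junk = 1,
                                       threshold = list(kind = "constant", b = 2))),
               "unknown")
  expect_error(parse_model_config(list(n = 2, mu = c(1, 1), t0 = 0.1,
                                       threshold = list(kind = "constant", b = 2,
                                                        lambda = 1))),
               "unknown")
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(hsdm_params(1, 1, 0, threshold_constant(1)), "n")
  expect_error(hsdm_params(2, c(1, 1), -0.1, threshold_constant(1)), "t0")
  expect_error(hsdm_params(2, c(1, 1, 1), 0.1, threshold_constant(1)), "mu")
  expect_error(threshold_constant(-1))
  expect_error(threshold_linear(3, -1))
})
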