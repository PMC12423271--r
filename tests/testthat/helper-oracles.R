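# Shared oracles and small utilities for the test suite.

# trapezoid CDF of a density sampled on the uniform grid t = dt, 2dt, ...,
# taking g(0) = 0
trap_cdf <- function(g, dt) {
  gg <- c(0, g)
  cumsum((gg[-1] + gg[-length(gg)]) / 2) * dt
}

# two-sample-style KS distance between an empirical sample and a model CDF
# tabulated on `times`
ks_distance <- function(sample, times, model_cdf) {
  max(abs(stats::ecdf(sample)(times) - pmin(model_cdf, 1)))
}

# random angle set drawn with the package's storage convention
random_angles <- function(n) {
  if (n == 2) return(stats::runif(1, 0, 2 * pi))
  c(stats::runif(n - 2, 0, pi), stats::runif(1, 0, 2 * pi))
}

# numeric central difference
central_diff <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# write a config list to a temp JSON file, returning its path
jsonlite_tmp <- function(cfg) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  f
}
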