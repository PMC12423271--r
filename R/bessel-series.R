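# Constant-threshold first-passage distribution of the radial (Bessel)
# process as a truncated eigenfunction series. This is the classical
# analytic route; it is exact in the limit of infinitely many terms but a
# finite truncation misbehaves for short times (see the vignette), which is
# why the integral-equation solver is the production path. Here it serves as
# the independent oracle for constant thresholds.

# cache of (roots, denominators) per (nu, k_terms)
.bessel_cache <- new.env(parent = emptyenv())

#' Positive zeros of the Bessel function of the first kind
#'
#' Computes the first `k_terms` positive zeros `j[nu, k]` of `J_nu` by Newton
#' iteration started from the McMahon asymptotic expansion, refined until
#' `|J_nu(z)| < 1e-12`.
#'
#' @param nu order, `nu >= 0`.
#' @param k_terms how many zeros.
#' @return Strictly increasing numeric vector of length `k_terms`.
#' @examples
#' bessel_zeros(0, 3)   # 2.4048, 5.5201, 8.6537
#' @export
bessel_zeros <- function(nu, k_terms) {
  stopifnot(is.numeric(nu), length(nu) == 1L, nu >= 0,
            is.numeric(k_terms), length(k_terms) == 1L, k_terms >= 1)
  k <- seq_len(k_terms)
  beta <- (k + nu / 2 - 0.25) * pi
  m <- 4 * nu^2
  # McMahon expansion: good start for all k when nu is moderate
  z <- beta - (m - 1) / (8 * beta) -
    4 * (m - 1) * (7 * m - 31) / (3 * (8 * beta)^3)
  for (iter in 1:50) {
    f <- besselJ(z, nu)
    if (all(abs(f) < 1e-12)) break
    # J'_nu(z) = J_{nu-1}(z) - (nu/z) J_nu(z)
    fp <- (nu / z) * f - besselJ(z, nu + 1)
    step <- f / fp
    step <- pmax(pmin(step, 0.5), -0.5)  # keep Newton inside the bracket
    z <- z - step
  }
  if (any(diff(z) <= 0) || any(abs(besselJ(z, nu)) > 1e-10))
    stop("Bessel zero computation failed to converge", call. = FALSE)
  z
}

bessel_series_table <- function(nu, k_terms) {
  key <- sprintf("%.12g_%d", nu, as.integer(k_terms))
  tab <- .bessel_cache[[key]]
  if (is.null(tab)) {
    roots <- bessel_zeros(nu, k_terms)
    tab <- list(nu = nu, roots = roots, denom = besselJ(roots, nu + 1),
                k_terms = as.integer(k_terms))
    .bessel_cache[[key]] <- tab
  }
  tab
}

check_series_args <- function(b, sigma, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be >= 2", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop("`b` must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
}

#' Series form of the constant-threshold first-passage distribution
#'
#' Cumulative distribution (`series_fpt_cdf`) and density
#' (`series_fpt_density`) of the first time a zero-drift `n`-dimensional
#' Wiener process started at the origin reaches radius `b`, as a truncated
#' series over Bessel eigenvalues: with `nu = (n-2)/2` and `j[nu,k]` the k-th
#' zero of `J_nu`,
#' \deqn{G(T) = 1 - \frac{1}{2^{\nu-1}\Gamma(\nu+1)} \sum_k
#'   \frac{j_{\nu,k}^{\nu-1}}{J_{\nu+1}(j_{\nu,k})}
#'   e^{-j_{\nu,k}^2 \sigma^2 T / (2 b^2)}}
#' \deqn{g(T) = \frac{\sigma^2}{2^{\nu} b^2 \Gamma(\nu+1)} \sum_k
#'   \frac{j_{\nu,k}^{\nu+1}}{J_{\nu+1}(j_{\nu,k})}
#'   e^{-j_{\nu,k}^2 \sigma^2 T / (2 b^2)}}
#'
#' For short times (roughly `T < 0.075 * b^2 / sigma^2` in two dimensions)
#' the truncated series is unreliable: terms decay slowly and the alternating
#' partial sums produce artificial oscillations, including negative density
#' values. Those values are returned as-is, not clamped, so the pathology can
#' be detected; likelihood evaluation never uses this path.
#'
#' @param t decision time(s), seconds (vectorized).
#' @param b constant boundary radius.
#' @param n dimension of the accumulation space.
#' @param sigma diffusion coefficient.
#' @param k_terms number of series terms (default 500).
#' @return Numeric vector the length of `t`.
#' @examples
#' series_fpt_cdf(1, b = 1, n = 2)
#' @export
series_fpt_cdf <- function(t, b, n, sigma = 1, k_terms = 500) {
  check_series_args(b, sigma, n)
  stopifnot(all(t >= 0))
  nu <- (n - 2) / 2
  tab <- bessel_series_table(nu, k_terms)
  coef <- tab$roots^(nu - 1) / tab$denom
  rate <- tab$roots^2 * sigma^2 / (2 * b^2)
  pref <- 1 / (2^(nu - 1) * gamma(nu + 1))
  vapply(t, function(ti) 1 - pref * sum(coef * exp(-rate * ti)), numeric(1))
}

#' @rdname series_fpt_cdf
#' @export
series_fpt_density <- function(t, b, n, sigma = 1, k_terms = 500) {
  check_series_args(b, sigma, n)
  stopifnot(all(t > 0))
  nu <- (n - 2) / 2
  tab <- bessel_series_table(nu, k_terms)
  coef <- tab$roots^(nu + 1) / tab$denom
  rate <- tab$roots^2 * sigma^2 / (2 * b^2)
  pref <- sigma^2 / (2^nu * b^2 * gamma(nu + 1))
  vapply(t, function(ti) pref * sum(coef * exp(-rate * ti)), numeric(1))
}

# individual (signed) series terms of the density at one time point,
# used to diagnose the short-time truncation pathology
series_density_terms <- function(t, b, n, sigma = 1, k_terms = 500) {
  check_series_args(b, sigma, n)
  nu <- (n - 2) / 2
  tab <- bessel_series_table(nu, k_terms)
  pref <- sigma^2 / (2^nu * b^2 * gamma(nu + 1))
  pref * tab$roots^(nu + 1) / tab$denom *
    exp(-tab$roots^2 * sigma^2 * t / (2 * b^2))
}

# smallest T at which the constant-threshold series CDF reaches `p`.
# The lower bracket starts past the short-time region where the truncated
# series oscillates (scale T/b^2; the CDF there is far below any p of use).
series_fpt_quantile <- function(p, b, n, sigma = 1, k_terms = 500) {
  stopifnot(p > 0.01, p < 1)
  lower <- 1e-3 * b^2 / sigma^2
  upper <- 2 * b^2 / sigma^2
  while (series_fpt_cdf(upper, b, n, sigma, k_terms) < p) upper <- upper * 2
  stats::uniroot(function(t) series_fpt_cdf(t, b, n, sigma, k_terms) - p,
                 lower = lower, upper = upper, tol = 1e-8)$root
}
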