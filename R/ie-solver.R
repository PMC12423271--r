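#' Free transition density of the squared-Bessel process
#'
#' Transition density of `Y(t) = R(t)^2`, the squared distance from the
#' origin of a zero-drift `n`-dimensional Wiener process, in the absence of
#' any boundary:
#' \deqn{f[y, t | y_0, \tau] = \frac{1}{2(t-\tau)}
#'   \left(\frac{y}{y_0}\right)^{(n-2)/4}
#'   \exp\!\left(-\frac{y+y_0}{2(t-\tau)}\right)
#'   I_{n/2-1}\!\left(\frac{\sqrt{y y_0}}{t-\tau}\right).}
#' For the origin start `y0 = 0` the small-argument limit of the modified
#' Bessel function gives the analytic form
#' `f = y^(n/2-1) exp(-y/(2(t-tau))) / ((2(t-tau))^(n/2) Gamma(n/2))`,
#' a gamma density in `y` with shape `n/2` and scale `2(t-tau)`.
#'
#' @param y state (squared radius), `>= 0` (vectorized).
#' @param t later time.
#' @param y0 starting state, `>= 0`.
#' @param tau earlier time, `t > tau`.
#' @param n dimension.
#' @return Density values over `y`.
#' @export
free_density <- function(y, t, y0 = 0, tau = 0, n = 2) {
  stopifnot(n >= 2, all(y >= 0), all(y0 >= 0))
  if (!(t > tau)) stop("`t` must exceed `tau`", call. = FALSE)
  d <- t - tau
  nu <- n / 2 - 1
  m <- max(length(y), length(y0))
  y <- rep_len(y, m); y0 <- rep_len(y0, m)
  # origin start: small-argument limit of I_nu gives a gamma density in y
  out_origin <- y^(n / 2 - 1) * exp(-y / (2 * d)) /
    ((2 * d)^(n / 2) * gamma(n / 2))
  # exp(-(y+y0)/(2d)) I_nu(z) = exp(-(sqrt(y)-sqrt(y0))^2/(2d)) [e^-z I_nu(z)]:
  # the scaled form stays finite for small d
  z <- sqrt(pmax(y * y0, 0)) / d
  yy0 <- ifelse(y0 > 0, y0, 1)  # placeholder, masked below
  out <- exp(-(sqrt(y) - sqrt(y0))^2 / (2 * d)) * (y / yy0)^(nu / 2) *
    besselI(z, nu, expon.scaled = TRUE) / (2 * d)
  out <- ifelse(y0 == 0, out_origin, out)
  zero <- y == 0 & y0 > 0
  if (any(zero))
    out[zero] <- if (n == 2) exp(-y0[zero] / (2 * d)) / (2 * d) else 0
  out
}

#' Volterra kernel of the first-passage problem
#'
#' The non-singular kernel of the second-kind Volterra equation for the
#' first-passage density of the squared-Bessel process through the squared
#' boundary `S(t)`:
#' \deqn{\Psi[S(t), t | y, \tau] = \frac{e^{-(S+y)/(2\Delta)}}{2\Delta}
#'   \left(\frac{S}{y}\right)^{\frac{n-2}{4}}
#'   \left[\left(S'(t) - \frac{S}{\Delta} + \mathcal K(t)\right)
#'   I_{n/2-1}(z) + z\, I_{n/2}(z)\right]}
#' with `z = sqrt(y S)/Delta`, `Delta = t - tau`, and
#' `K(t) = (n - 1 - S'(t)) / 2`. The kernel vanishes as `tau -> t-` when
#' `y = S(tau)`, which is what makes the discretized equation well behaved.
#' `y = 0` is handled by its analytic limit, and the Bessel/exponential
#' product is evaluated in exponentially scaled form so small `Delta` does
#' not overflow.
#'
#' @param t evaluation time (strictly below the threshold's singular time).
#' @param tau earlier time, `0 <= tau < t` (vectorized with `y`).
#' @param y squared radius at `tau`, `>= 0`.
#' @param n dimension.
#' @param threshold an `hsdm_threshold`.
#' @return Kernel values.
#' @export
kernel_psi <- function(t, tau, y, n, threshold) {
  stopifnot(inherits(threshold, "hsdm_threshold"), n >= 2,
            all(tau >= 0), all(y >= 0))
  if (any(t >= threshold$t_singular))
    stop("kernel undefined at or beyond the threshold's singular time",
         call. = FALSE)
  if (any(t <= tau)) stop("`t` must exceed `tau`", call. = FALSE)
  m <- max(length(t), length(tau), length(y))
  t <- rep_len(t, m); tau <- rep_len(tau, m); y <- rep_len(y, m)
  .psi_kernel_cpp(t, tau, y, threshold$S(t), threshold$dSdt(t), as.integer(n))
}

#' Solve for the first-passage density on a uniform time grid
#'
#' Discretizes the second-kind Volterra equation for the first-passage
#' density `g` of the squared-Bessel process (equivalently: of the radial
#' part of a zero-drift `n`-dimensional Wiener process started at the
#' origin) through the boundary `b(t)`, using the rectangle left-point
#' scheme:
#' `g(dt) = -2 Psi[S(dt), dt | 0, 0]`,
#' `g(i dt) = -2 Psi[S(i dt), i dt | 0, 0] +
#'    2 dt * sum_{j<i} g(j dt) Psi[S(i dt), i dt | S(j dt), j dt]`.
#' The scheme is first-order accurate in `delta_t` and costs `O(K^2)` kernel
#' evaluations; for constant thresholds the kernel depends only on the lag
#' and the solve reduces to `K` kernel evaluations plus the recursion.
#'
#' If `t_max` is omitted it defaults to the time where the constant-threshold
#' series CDF reaches 0.999 and, for collapsing thresholds, is additionally
#' capped at 98% of the singular time; grids never extend past
#' `t_singular - delta_t`.
#'
#' @param n dimension of the accumulation space.
#' @param threshold an `hsdm_threshold`.
#' @param delta_t grid step in seconds.
#' @param t_max horizon in seconds (optional; see Details).
#' @return An object of class `fpt_grid`: list with `times`, `g`, `delta_t`,
#'   `t_max`, `n`, `threshold`.
#' @examples
#' grid <- solve_fpt(2, threshold_constant(1), delta_t = 0.01)
#' sum(grid$g) * grid$delta_t  # ~ 1
#' @export
solve_fpt <- function(n, threshold, delta_t, t_max = NULL) {
  stopifnot(inherits(threshold, "hsdm_threshold"),
            is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  ts_ <- threshold$t_singular
  if (is.null(t_max)) {
    b_ref <- threshold$b(0)
    t_max <- series_fpt_quantile(0.999, b_ref, n)
    if (is.finite(ts_)) t_max <- min(t_max, 0.98 * ts_)
  }
  # clamp strictly below the singular point: the kernel is undefined at b = 0
  cap <- if (is.finite(ts_)) ts_ - delta_t else Inf
  if (t_max > cap) {
    if (cap < delta_t)
      stop("grid horizon would cross the threshold's singular time at t = ",
           signif(ts_, 6), "; use a smaller delta_t", call. = FALSE)
    t_max <- cap
  }
  K <- max(1L, as.integer(floor(t_max / delta_t + 1e-9)))
  times <- delta_t * seq_len(K)
  g <- .ie_solve_cpp(times, threshold$S(times), threshold$dSdt(times),
                     n, delta_t, threshold$kind == "constant")
  structure(list(times = times, g = g, delta_t = delta_t,
                 t_max = K * delta_t, n = n, threshold = threshold),
            class = "fpt_grid")
}

#' @export
print.fpt_grid <- function(x, ...) {
  cat(sprintf(
    "First-passage density grid: n = %d, %s threshold, delta_t = %g s, %d steps (t_max = %g s)\n",
    x$n, x$threshold$kind, x$delta_t, length(x$g), x$t_max))
  cat(sprintf("  mass on grid (trapezoid): %.4f\n", grid_mass(x)))
  invisible(x)
}

# trapezoid mass over [0, t_max], taking g(0) = 0
grid_mass <- function(grid) {
  g <- c(0, grid$g)
  sum((g[-1] + g[-length(g)]) / 2) * grid$delta_t
}

#' Evaluate a solved grid at arbitrary times
#'
#' Linear interpolation between grid nodes, with `g(0) = 0`; times at or
#' below zero give 0, and times beyond the grid horizon give 0 (the horizon
#' rule keeps the mass beyond `t_max` negligible, and the likelihood floor
#' handles such trials).
#'
#' @param grid an [solve_fpt()] result.
#' @param t times (seconds), vectorized.
#' @return Interpolated density values.
#' @export
density_at <- function(grid, t) {
  stopifnot(inherits(grid, "fpt_grid"))
  dt <- grid$delta_t
  g0 <- c(0, grid$g)
  K <- length(grid$g)
  out <- numeric(length(t))
  ok <- is.finite(t) & t > 0 & t <= grid$t_max
  ti <- t[ok]
  i <- pmin(floor(ti / dt), K - 1)   # lower node index into g0 (0-based time i*dt)
  w <- (ti - i * dt) / dt
  out[ok] <- (1 - w) * g0[i + 1] + w * g0[i + 2]
  out
}

#' Marginal response-time density of an HSDM
#'
#' Integrates the joint density of decision time and response angle over the
#' response sphere, giving the predicted response-time distribution: with
#' `z = b(T) * ||mu|| / sigma^2`,
#' `m(T) = g(T) * exp(-||mu||^2 T / (2 sigma^2)) * Gamma(n/2) (2/z)^(n/2-1) I_{n/2-1}(z)`
#' (the spherical average of the change-of-measure factor), where
#' `T = rt - t0`.
#'
#' @param rt response times in seconds (vectorized).
#' @param params an [hsdm_params()] object.
#' @param grid optionally, a pre-solved [solve_fpt()] grid (after sigma
#'   rescaling); solved on demand otherwise.
#' @param delta_t grid step used when `grid` is not supplied.
#' @return Density values (per second).
#' @export
marginal_rt_density <- function(rt, params, grid = NULL, delta_t = 0.01) {
  stopifnot(inherits(params, "hsdm_params"))
  params <- normalize_sigma(params)
  if (is.null(grid))
    grid <- solve_fpt(params$n, params$threshold, delta_t)
  tt <- rt - params$t0
  g <- density_at(grid, tt)
  mu_norm <- sqrt(sum(params$mu^2))
  n <- params$n
  nu <- n / 2 - 1
  z <- params$threshold$b(pmax(tt, 0)) * mu_norm
  avg <- ifelse(z > 0,
                gamma(n / 2) * (2 / z)^nu *
                  besselI(z, nu, expon.scaled = TRUE) * exp(z - mu_norm^2 * tt / 2),
                exp(-mu_norm^2 * tt / 2))
  ifelse(tt > 0, g * avg, 0)
}
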