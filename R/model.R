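#' Decision-threshold specifications
#'
#' A threshold specification describes the radius `b(t)` of the absorbing
#' hyper-sphere as a function of decision time, together with the squared
#' boundary `S(t) = b(t)^2` and its time derivative, which are what the
#' integral-equation solver consumes. Three kinds are supported:
#'
#' * `threshold_constant(b)`: `b(t) = b`.
#' * `threshold_linear(b0, lambda)`: `b(t) = b0 - lambda * t`, the linear
#'   collapse. The boundary reaches zero at the singular time
#'   `t_singular = b0 / lambda`; solver grids are always truncated strictly
#'   below it, because the first-passage kernel is undefined at `b = 0`.
#' * `threshold_custom(b_fun, db_fun, t_singular)`: a user boundary. Only
#'   `b(t)` and `db/dt` are supplied; `S` and `dS/dt = 2 b db/dt` are derived
#'   internally so the pair can never be inconsistent.
#'
#' @param b boundary radius (evidence units), `b > 0`.
#' @param b0 initial radius of the collapsing boundary, `b0 > 0`.
#' @param lambda collapse slope (evidence units per second), `lambda > 0`.
#' @param b_fun function of time returning the boundary radius.
#' @param db_fun function of time returning `db/dt`.
#' @param t_singular first time at which `b(t) = 0` (`Inf` if never).
#' @return An object of class `hsdm_threshold` with elements `kind`, `params`,
#'   and functions `b(t)`, `S(t)`, `dSdt(t)`, plus `t_singular`.
#' @examples
#' th <- threshold_linear(b0 = 3, lambda = 1.5)
#' th$b(0)          # 3
#' th$t_singular    # 2
#' @export
threshold_constant <- function(b) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  force(b)
  structure(list(
    kind = "constant",
    params = list(b = b),
    b = function(t) rep_len(b, length(t)),
    S = function(t) rep_len(b^2, length(t)),
    dSdt = function(t) rep_len(0, length(t)),
    t_singular = Inf
  ), class = "hsdm_threshold")
}

#' @rdname threshold_constant
#' @export
threshold_linear <- function(b0, lambda) {
  stopifnot(is.numeric(b0), length(b0) == 1L, is.finite(b0), b0 > 0,
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda > 0)
  structure(list(
    kind = "linear",
    params = list(b0 = b0, lambda = lambda),
    b = function(t) pmax(b0 - lambda * t, 0),
    S = function(t) pmax(b0 - lambda * t, 0)^2,
    dSdt = function(t) ifelse(t < b0 / lambda, -2 * lambda * (b0 - lambda * t), 0),
    t_singular = b0 / lambda
  ), class = "hsdm_threshold")
}

#' @rdname threshold_constant
#' @export
threshold_custom <- function(b_fun, db_fun, t_singular = Inf) {
  stopifnot(is.function(b_fun), is.function(db_fun),
            is.numeric(t_singular), length(t_singular) == 1L, t_singular > 0)
  structure(list(
    kind = "custom",
    params = list(),
    b = b_fun,
    S = function(t) b_fun(t)^2,
    # derived, not user-supplied: keeps S and dS/dt consistent by construction
    dSdt = function(t) 2 * b_fun(t) * db_fun(t),
    t_singular = t_singular
  ), class = "hsdm_threshold")
}

#' @export
print.hsdm_threshold <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  else "user-defined b(t)"
  cat(sprintf("HSDM threshold [%s]: %s", x$kind, ps))
  if (is.finite(x$t_singular))
    cat(sprintf(", singular at t = %g s", x$t_singular))
  cat("\n")
  invisible(x)
}

#' HSDM parameter set
#'
#' Bundles the full parameter vector of one hyper-spherical diffusion model:
#' the dimension `n` of the accumulation space, the drift vector `mu`
#' (evidence units per second), the diffusion coefficient `sigma`, the
#' non-decision time `t0` (seconds), and a threshold specification.
#'
#' All internal solvers assume `sigma = 1` (the usual convention for this
#' model family, which fixes the scale of the evidence space). A general
#' `sigma` is accepted here and removed once on entry to any solver by the
#' exact rescaling `X -> X/sigma`, i.e. `mu -> mu/sigma`, `b -> b/sigma`,
#' which leaves the time axis untouched.
#'
#' @param n integer dimension of the accumulation space, `n >= 2`.
#' @param mu drift vector of length `n`.
#' @param t0 non-decision time in seconds, `t0 >= 0`.
#' @param threshold an [threshold_constant()] / [threshold_linear()] /
#'   [threshold_custom()] object.
#' @param sigma diffusion coefficient, `> 0` (default 1).
#' @return An object of class `hsdm_params`.
#' @examples
#' hsdm_params(n = 2, mu = c(6, 6), t0 = 0.3, threshold = threshold_constant(5))
#' @export
hsdm_params <- function(n, mu, t0, threshold, sigma = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != n || any(!is.finite(mu)))
    stop("`mu` must be a finite numeric vector of length n", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("`t0` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single number > 0", call. = FALSE)
  if (!inherits(threshold, "hsdm_threshold"))
    stop("`threshold` must be an hsdm_threshold object", call. = FALSE)
  if (!(threshold$b(0) > 0))
    stop("threshold must satisfy b(0) > 0", call. = FALSE)
  structure(list(n = n, mu = as.numeric(mu), sigma = sigma, t0 = t0,
                 threshold = threshold),
            class = "hsdm_params")
}

#' @export
print.hsdm_params <- function(x, ...) {
  cat(sprintf("HSDM parameters: n = %d, mu = (%s), sigma = %g, t0 = %g s\n",
              x$n, paste(signif(x$mu, 4), collapse = ", "), x$sigma, x$t0))
  print(x$threshold)
  invisible(x)
}

# Rescale to the sigma = 1 convention used by every solver: X -> X/sigma,
# so mu -> mu/sigma and b -> b/sigma while time is unchanged.
normalize_sigma <- function(params) {
  if (params$sigma == 1) return(params)
  s <- params$sigma
  th <- params$threshold
  th2 <- switch(th$kind,
    constant = threshold_constant(th$params$b / s),
    linear   = threshold_linear(th$params$b0 / s, th$params$lambda / s),
    custom   = {
      bf <- th$b
      dS <- th$dSdt
      threshold_custom(function(t) bf(t) / s,
                       function(t) dS(t) / (2 * bf(t)) / s,
                       t_singular = th$t_singular)
    })
  hsdm_params(params$n, params$mu / s, params$t0, th2, sigma = 1)
}

#' Precision index of a constant-threshold HSDM
#'
#' The model's index of response precision, the product of stimulus quality
#' and response caution: `kappa = b * ||mu|| / sigma^2`. It is defined only
#' for constant thresholds; with a collapsing boundary the amount of evidence
#' required varies over time and no single precision index exists.
#'
#' @param params an [hsdm_params()] object with a constant threshold.
#' @return Non-negative scalar.
#' @examples
#' p <- hsdm_params(2, c(6, 6), 0.3, threshold_constant(5))
#' hsdm_kappa(p)  # 5 * sqrt(72) = 42.43
#' @export
hsdm_kappa <- function(params) {
  stopifnot(inherits(params, "hsdm_params"))
  if (params$threshold$kind != "constant")
    stop("kappa is undefined for time-dependent thresholds", call. = FALSE)
  params$threshold$params$b * sqrt(sum(params$mu^2)) / params$sigma^2
}

#' Spherical/Cartesian response coordinates
#'
#' Converts between the stopping point of the accumulator on the boundary
#' sphere and its angular representation. With `n - 1` angles
#' `phi[1], ..., phi[n-1]` the Cartesian stopping point is the nested
#' sine/cosine product
#' `X1 = b cos(phi1)`, `X2 = b sin(phi1) cos(phi2)`, ...,
#' `Xn = b sin(phi1) ... sin(phi[n-2]) sin(phi[n-1])`.
#' Convention: `phi[1], ..., phi[n-2]` lie in `[0, pi]` and the last angle in
#' `[0, 2*pi)`; for `n = 2` the single angle lies in `[0, 2*pi)`.
#'
#' @param b_at_t boundary radius at the stopping time, `> 0`.
#' @param phi numeric vector of `n - 1` angles (radians).
#' @param x numeric vector, the Cartesian point (nonzero).
#' @return `spherical_to_cartesian()`: a numeric vector of length `n` with
#'   Euclidean norm `b_at_t`. `cartesian_to_spherical()`: a list with
#'   `radius` and `phi`.
#' @examples
#' spherical_to_cartesian(1, 0)            # (1, 0)
#' cartesian_to_spherical(c(3, 4))$radius  # 5
#' @export
spherical_to_cartesian <- function(b_at_t, phi) {
  if (!is.numeric(b_at_t) || length(b_at_t) != 1L || !is.finite(b_at_t) ||
      b_at_t <= 0)
    stop("boundary radius must be a single positive number", call. = FALSE)
  check_angles(phi)
  b_at_t * unit_vector_from_angles(phi)
}

# unit vector for one angle set (length n - 1)
unit_vector_from_angles <- function(phi) {
  m <- length(phi)
  s <- cumprod(c(1, sin(phi)))      # s[k] = prod_{i<k} sin(phi_i)
  c(s[seq_len(m)] * cos(phi), s[m + 1L])
}

# rows of `phi_mat` are angle sets; returns matrix of unit row vectors
unit_vectors_from_angle_matrix <- function(phi_mat) {
  phi_mat <- as.matrix(phi_mat)
  m <- ncol(phi_mat)
  sn <- sin(phi_mat)
  s <- if (m == 1L) cbind(1, sn)
       else cbind(1, t(apply(sn, 1L, cumprod)))
  cbind(s[, seq_len(m), drop = FALSE] * cos(phi_mat), s[, m + 1L])
}

check_angles <- function(phi) {
  if (!is.numeric(phi) || length(phi) < 1L || any(!is.finite(phi)))
    stop("`phi` must be a finite numeric vector of length n - 1", call. = FALSE)
  m <- length(phi)
  tol <- 1e-9
  if (m > 1L && (any(phi[-m] < -tol) || any(phi[-m] > pi + tol)))
    stop("angles phi[1..n-2] must lie in [0, pi]", call. = FALSE)
  if (phi[m] < -tol || phi[m] >= 2 * pi + tol)
    stop("the last angle must lie in [0, 2*pi)", call. = FALSE)
  invisible(phi)
}

#' @rdname spherical_to_cartesian
#' @export
cartesian_to_spherical <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)))
    stop("`x` must be a finite numeric vector of length >= 2", call. = FALSE)
  r <- sqrt(sum(x^2))
  if (r == 0) stop("the zero vector has no angular representation", call. = FALSE)
  n <- length(x)
  phi <- numeric(n - 1L)
  if (n > 2L) {
    # tail norms: ||x[k+1 .. n]||
    tail_norm <- sqrt(rev(cumsum(rev(x^2))))
    for (k in seq_len(n - 2L)) phi[k] <- atan2(tail_norm[k + 1L], x[k])
  }
  last <- atan2(x[n], x[n - 1L]) %% (2 * pi)
  phi[n - 1L] <- last
  list(radius = r, phi = phi)
}

# Surface area of the unit (n-1)-sphere embedded in R^n.
sphere_surface_area <- function(n) 2 * pi^(n / 2) / gamma(n / 2)

#' Read an HSDM model configuration from JSON
#'
#' Schema:
#' `{"n": int, "mu": [..], "sigma": 1.0, "t0": float,`
#' `"threshold": {"kind": "constant"|"linear", "b": .. | "b0": .., "lambda": ..}}`.
#' Unknown keys are rejected.
#'
#' @param config path to a JSON file, or an already-parsed list.
#' @return An [hsdm_params()] object.
#' @export
parse_model_config <- function(config) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  known <- c("n", "mu", "sigma", "t0", "threshold")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown model config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("n", "mu", "t0", "threshold"), names(cfg))
  if (length(miss))
    stop("missing model config keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  th <- parse_threshold_config(cfg$threshold)
  hsdm_params(cfg$n, unlist(cfg$mu), cfg$t0, th,
              sigma = if (is.null(cfg$sigma)) 1 else cfg$sigma)
}

parse_threshold_config <- function(tc) {
  if (is.null(tc$kind)) stop("threshold config needs a `kind`", call. = FALSE)
  switch(tc$kind,
    constant = {
      extra <- setdiff(names(tc), c("kind", "b"))
      if (length(extra)) stop("unknown threshold keys: ",
                              paste(extra, collapse = ", "), call. = FALSE)
      threshold_constant(tc$b)
    },
    linear = {
      extra <- setdiff(names(tc), c("kind", "b0", "lambda"))
      if (length(extra)) stop("unknown threshold keys: ",
                              paste(extra, collapse = ", "), call. = FALSE)
      threshold_linear(tc$b0, tc$lambda)
    },
    stop("unsupported threshold kind: ", tc$kind, call. = FALSE))
}
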