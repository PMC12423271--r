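# Joint density of decision time and response angle, and the trial-set
# negative log-likelihood. The zero-drift first-passage density g comes from
# the integral-equation grid; nonzero drift enters through the Girsanov
# change-of-measure factor exp(mu . X(T) - ||mu||^2 T / 2) (sigma = 1 after
# rescaling), with X(T) the stopping point on the boundary sphere of radius
# b(T) -- for collapsing thresholds the radius at the *stopping time*, not
# b(0). Densities are reported with respect to (T, uniform surface measure),
# hence the constant 1/A_{n-1} with A_{n-1} = 2 pi^{n/2} / Gamma(n/2); an
# additive constant in log-likelihood, irrelevant to ML estimation.

# likelihood floor: guards trials outside the grid support and tiny/negative
# discretization artifacts, keeping the optimizer's objective finite
LIK_FLOOR <- 1e-10

#' Joint density of response time and response angles
#'
#' Evaluates the HSDM joint density of one or more (rt, phi) observations:
#' \deqn{P(T, \varphi) = \exp\!\left[\frac{\mu \cdot X(T)}{\sigma^2}
#'   - \frac{\|\mu\|^2 T}{2\sigma^2}\right] g(T) / A_{n-1},}
#' where `T = rt - t0`, `X(T)` is the Cartesian stopping point on the sphere
#' of radius `b(T)`, and `g` is the zero-drift first-passage density from the
#' solved grid. Observations with `T <= 0` (or beyond the grid horizon)
#' receive the likelihood floor `1e-10`.
#'
#' @param rt response time(s), seconds.
#' @param phi numeric vector of `n - 1` angles, or a matrix with one row per
#'   element of `rt`.
#' @param params an [hsdm_params()] object.
#' @param grid a grid from [solve_fpt()] for the (sigma-rescaled) threshold
#'   and dimension of `params`; solved on demand when `NULL`.
#' @param delta_t grid step used when `grid` is `NULL`.
#' @return Joint density values (per second per unit surface area).
#' @export
joint_density <- function(rt, phi, params, grid = NULL, delta_t = 0.02) {
  stopifnot(inherits(params, "hsdm_params"))
  params <- normalize_sigma(params)
  phi <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1L)
  if (ncol(phi) != params$n - 1L)
    stop("`phi` must have n - 1 = ", params$n - 1L, " angle(s) per trial",
         call. = FALSE)
  if (nrow(phi) != length(rt))
    stop("`rt` and `phi` disagree in the number of trials", call. = FALSE)
  if (is.null(grid))
    grid <- solve_fpt(params$n, params$threshold,
                      delta_t, t_max = fit_horizon(max(rt), delta_t, params$threshold))
  u <- unit_vectors_from_angle_matrix(phi)
  joint_density_units(rt, u, params, grid)
}

# internal fast path: `u` is the precomputed matrix of unit stopping vectors
joint_density_units <- function(rt, u, params, grid) {
  tt <- rt - params$t0
  g <- density_at(grid, tt)
  b_T <- params$threshold$b(pmax(tt, 0))
  expo <- b_T * as.numeric(u %*% params$mu) - 0.5 * sum(params$mu^2) * tt
  dens <- exp(expo) * g / sphere_surface_area(params$n)
  ifelse(tt > 0, pmax(dens, LIK_FLOOR), LIK_FLOOR)
}

# grid horizon used for fitting: just past the largest observed rt (T =
# rt - t0 never exceeds it); solve_fpt caps it below any singular time
fit_horizon <- function(max_rt, delta_t, threshold) {
  h <- max_rt + 5 * delta_t
  if (is.finite(threshold$t_singular)) h <- min(h, threshold$t_singular - delta_t)
  h
}

#' Negative log-likelihood of a trial table
#'
#' Sums `-log` of the joint density over all trials, with the likelihood
#' floor applied per trial so the objective is finite for any parameter
#' vector inside the bounds. One first-passage grid is solved per call and
#' shared across trials.
#'
#' @param trials a data frame with column `rt` and angle columns
#'   `phi_1, ..., phi_{n-1}` (see [read_trials()]).
#' @param params an [hsdm_params()] object.
#' @param delta_t likelihood grid step in seconds.
#' @param grid optional pre-solved grid (used as-is).
#' @return A single number, `-sum(log(max(joint, 1e-10)))`.
#' @export
neg_log_likelihood <- function(trials, params, delta_t = 0.02, grid = NULL) {
  tab <- validate_trials(trials)
  params <- normalize_sigma(params)
  if (ncol(tab$phi) != params$n - 1L)
    stop("trial table has ", ncol(tab$phi) + 1L,
         " response dimensions but the model has n = ", params$n,
         call. = FALSE)
  if (is.null(grid))
    grid <- solve_fpt(params$n, params$threshold, delta_t,
                      t_max = fit_horizon(max(tab$rt), delta_t, params$threshold))
  u <- unit_vectors_from_angle_matrix(tab$phi)
  -sum(log(joint_density_units(tab$rt, u, params, grid)))
}

# ---- trial tables ----------------------------------------------------------

angle_cols <- function(df) grep("^phi_[0-9]+$", names(df), value = TRUE)

validate_trials <- function(trials, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  if (!is.data.frame(trials) || !"rt" %in% names(trials))
    stop("trials must be a data frame with an `rt` column", where, call. = FALSE)
  ac <- angle_cols(trials)
  if (length(ac) < 1L)
    stop("trials must have angle columns phi_1[, phi_2, ...]", where,
         call. = FALSE)
  ac <- paste0("phi_", seq_along(ac))
  if (!all(ac %in% names(trials)))
    stop("angle columns must be consecutively numbered phi_1, phi_2, ...",
         where, call. = FALSE)
  rt <- trials$rt
  bad <- which(!is.finite(rt) | rt <= 0)
  if (length(bad))
    stop("non-positive or missing rt", where, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  phi <- as.matrix(trials[ac])
  m <- ncol(phi)
  tol <- 1e-9
  bad <- which(!is.finite(phi[, m]) | phi[, m] < -tol | phi[, m] >= 2 * pi + tol)
  if (m > 1L) {
    mid <- phi[, -m, drop = FALSE]
    idx <- which(!is.finite(mid) | mid < -tol | mid > pi + tol)
    bad <- union(bad, ((idx - 1L) %% nrow(phi)) + 1L)
  }
  if (length(bad))
    stop("angle out of range", where, " at row(s) ",
         paste(utils::head(sort(bad), 5), collapse = ", "), call. = FALSE)
  list(rt = rt, phi = phi, n = m + 1L)
}

#' Read and write trial tables
#'
#' Trial CSVs have a header `rt,phi_1[,phi_2,...]`; response times are in
#' seconds, angles in radians (`phi_1..phi_{n-2}` in `[0, pi]`, the last
#' angle in `[0, 2*pi)`). The reader validates ranges and reports offending
#' row numbers.
#'
#' @param path file path.
#' @param trials data frame with columns `rt`, `phi_1`, ...
#' @return `read_trials()` returns the validated data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  validate_trials(df, file = path)
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
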