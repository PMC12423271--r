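#' Simulate HSDM trials by Euler-Maruyama integration
#'
#' Integrates the n-dimensional accumulation process
#' `dX = mu dt + sigma dW` from the origin with step `dt_sim`, stopping each
#' trial at the first step where `||X(t)|| >= b(t)`. The discrete exit point
#' is projected radially back onto the boundary sphere of radius `b(t)` for
#' the reported angles (no bridge correction; the bias this leaves is
#' controlled by the default `dt_sim = 1e-3` and quantified by a refinement
#' test). Reported `rt = t + t0`.
#'
#' For collapsing thresholds the boundary reaches zero at `t_singular`, where
#' any accumulator position is absorbed; trials alive at that point are
#' stopped there with the angle of their current position, mirroring the
#' fast-guess behaviour of a fully collapsed boundary. Trials still alive at
#' `max_time` (constant threshold only) are censored: excluded from the
#' output with their count in `attr(, "censored")` and a message.
#'
#' @param params an [hsdm_params()] object.
#' @param n_trials number of trials.
#' @param dt_sim integration step, seconds (default 1e-3).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param max_time censoring horizon in seconds (default 120).
#' @return Data frame with columns `rt`, `phi_1`, ...; attribute `censored`
#'   holds the number of excluded trials.
#' @examples
#' p <- hsdm_params(2, c(2, 1), 0.3, threshold_constant(2))
#' head(simulate_trials(p, 100, seed = 1))
#' @export
simulate_trials <- function(params, n_trials, dt_sim = 1e-3, seed = NULL,
                            max_time = 120) {
  stopifnot(inherits(params, "hsdm_params"), n_trials >= 1,
            dt_sim > 0, max_time > 0)
  params <- normalize_sigma(params)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  n <- params$n
  th <- params$threshold
  ts_ <- th$t_singular
  mu_step <- params$mu * dt_sim
  sd_step <- sqrt(dt_sim)

  # only positions of still-active trials are kept, so late steps touch few rows
  Xa <- matrix(0, nrow = n_trials, ncol = n)
  ids <- seq_len(n_trials)
  dec_t <- rep(NA_real_, n_trials)
  stop_x <- matrix(NA_real_, nrow = n_trials, ncol = n)
  t <- 0
  while (nrow(Xa) && t < max_time) {
    t <- t + dt_sim
    na <- nrow(Xa)
    Xa <- Xa + matrix(mu_step, nrow = na, ncol = n, byrow = TRUE) +
      sd_step * matrix(stats::rnorm(na * n), ncol = n)
    if (t >= ts_) {
      # boundary fully collapsed: every remaining trial is absorbed
      dec_t[ids] <- ts_
      stop_x[ids, ] <- Xa
      ids <- integer(0)
      Xa <- Xa[integer(0), , drop = FALSE]
      break
    }
    hit <- rowSums(Xa^2) >= th$b(t)^2
    if (any(hit)) {
      idx <- ids[hit]
      dec_t[idx] <- t
      stop_x[idx, ] <- Xa[hit, , drop = FALSE]
      ids <- ids[!hit]
      Xa <- Xa[!hit, , drop = FALSE]
    }
  }
  censored <- length(ids)
  if (censored > 0)
    message(censored, " trial(s) censored at max_time = ", max_time, " s")
  done <- which(!is.na(dec_t))
  if (n == 2L) {
    phi <- matrix(atan2(stop_x[done, 2L], stop_x[done, 1L]) %% (2 * pi),
                  ncol = 1L)
  } else {
    phi <- t(vapply(done, function(i) cartesian_to_spherical(stop_x[i, ])$phi,
                    numeric(n - 1L)))
  }
  out <- data.frame(rt = dec_t[done] + params$t0)
  for (k in seq_len(n - 1L)) out[[paste0("phi_", k)]] <- phi[, k]
  attr(out, "censored") <- censored
  out
}
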