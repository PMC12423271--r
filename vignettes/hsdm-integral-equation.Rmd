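---
title: "First-passage densities and likelihoods for hyper-spherical diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-passage densities and likelihoods for hyper-spherical diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdmie)
```

## The model

The hyper-spherical diffusion model (HSDM) describes decisions on a
continuous response scale — recalling a colour on a colour wheel, judging a
motion direction, setting a price. Evidence is an $n$-dimensional Wiener
process started at the origin,
$$d\mathbf{X}(t) = \boldsymbol\mu\,dt + \sigma\,d\mathbf{W}(t),$$
absorbed the first time its Euclidean norm reaches the boundary radius
$b(t)$. The angle of the hitting point is the response; the hitting time
plus a non-decision latency $t_0$ is the response time,
$RT = T + t_0$. The drift vector $\boldsymbol\mu$ carries stimulus quality
(direction = the true response, norm = signal strength); $b$ carries
response caution. For a constant threshold the precision index is
$\kappa = b\|\boldsymbol\mu\|/\sigma^2$ (`hsdm_kappa()`).

A *collapsing* threshold $b(t) = b_0 - \lambda t$ encodes urgency: later
decisions need less evidence and are more variable. The slope $\lambda$ is
the parameter of scientific interest when asking whether people grow
impatient within a decision.

Throughout, $\sigma$ fixes the scale of the evidence space and all solvers
assume $\sigma = 1$; a general $\sigma$ is removed on entry by the exact
rescaling $\mathbf X \to \mathbf X/\sigma$, $\boldsymbol\mu \to
\boldsymbol\mu/\sigma$, $b \to b/\sigma$, which leaves hitting times
unchanged.

## Two routes to the first-passage density

**Series route (constant thresholds only).** The radial part of the
zero-drift process is a Bessel process, and its first-passage density
through a constant $b$ has a classical eigenfunction series over the zeros
$j_{\nu,k}$ of $J_\nu$, $\nu = (n-2)/2$ (`series_fpt_density()`,
`series_fpt_cdf()`). A finite truncation, however, converges slowly at
short times: with 500 terms and a high threshold the truncated density
oscillates and even turns negative for small $T$ (visible with
`series_fpt_density(seq(0.005, 0.1, 0.005), b = 5, n = 2)`). We return
those values unclamped so the pathology is observable; nothing in the
likelihood path ever calls the series. Its role here is to be the
independent oracle for constant thresholds.

**Integral-equation route (the production path).** The squared radius
$Y = R^2$ is a squared-Bessel (Feller) process, $dY = n\,dt +
2\sqrt{Y}\,dW$. Its first-passage density $g$ through the squared boundary
$S(t) = b^2(t)$ solves a second-kind Volterra equation
$$g(t) = -2\Psi[S(t), t \mid y_0, 0] + 2\int_0^t g(\tau)\,
\Psi[S(t), t \mid S(\tau), \tau]\,d\tau,$$
whose kernel $\Psi$ (built from the free squared-Bessel transition density;
see `kernel_psi()`) vanishes as $\tau \to t^-$, so the equation is
non-singular and a plain rectangle left-point discretization converges as
the step $\Delta t \to 0$ (`solve_fpt()`). This works for *any*
sufficiently smooth $b(t)$, which is what makes collapsing-threshold
likelihoods tractable.

Two numerical points the equations leave open:

* **Origin start.** The model starts at $y_0 = 0$, where the kernel's
  $(S/y)^{(n-2)/4} I_{\nu}(\sqrt{yS}/\Delta)$ product is an indeterminate
  form. We use its analytic limit (via $I_\nu(z) \sim (z/2)^\nu /
  \Gamma(\nu+1)$) rather than an arbitrary small offset, so the first-step
  term is exact.
* **Overflow.** $e^{-(S+y)/(2\Delta)} I_\nu(\sqrt{yS}/\Delta)$ overflows
  for small $\Delta$ if evaluated naively; we evaluate it as
  $e^{-(\sqrt S - \sqrt y)^2/(2\Delta)}\,[e^{-z} I_\nu(z)]$ with
  exponentially scaled Bessel functions. For the orders the solver meets
  ($\nu \in \{0, \tfrac12, 1, \tfrac32, 2\}$, i.e. $n \in \{2,3,4\}$) the
  scaled functions are evaluated by dedicated Taylor/asymptotic code or
  half-integer closed forms (accurate to ~$10^{-10}$, verified against R's
  `besselI`); other orders fall back to the general routine.

Against the series oracle, the solver at $\Delta t = 0.01$ agrees to better
than $10^{-3}$ (in practice ~$10^{-6}$) across $n \in \{2,3,4\}$,
$b \in \{1,2,5\}$, and the convergence in $\Delta t$ is first order or
better (half-integer orders converge much faster).

```{r oracle}
grid <- solve_fpt(2, threshold_constant(2), delta_t = 0.01, t_max = 6)
idx <- grid$times >= 0.3
max(abs(grid$g[idx] - series_fpt_density(grid$times[idx], b = 2, n = 2)))
```

**Grid conventions.** The grid horizon defaults to the time where the
constant-threshold series CDF reaches 0.999 (for collapsing thresholds,
additionally capped at 98% of the singular time $t_\mathrm{sing} =
b_0/\lambda$, and always strictly below $t_\mathrm{sing} - \Delta t$: the
kernel is undefined at $b = 0$). When fitting, the horizon is the largest
observed response time plus $5\Delta t$. Off-grid times are evaluated by
linear interpolation with $g(0) = 0$; times beyond the horizon return 0 and
are caught by the likelihood floor. Tiny negative excursions of the
discretized $g$ (bounded by about $10^{-4}$ at $\Delta t \le 0.02$) are
likewise absorbed by the floor.

## From zero drift to the joint likelihood

Drift enters through the Girsanov change of measure. The joint density of
decision time and hitting angle is
$$P(T, \varphi) = \exp\!\Big[\tfrac{1}{\sigma^2}\boldsymbol\mu \cdot
\mathbf X(T) - \tfrac{\|\boldsymbol\mu\|^2}{2\sigma^2} T\Big]\,
g(T)\,/\,A_{n-1},$$
where $\mathbf X(T)$ is the stopping point on the sphere of radius $b(T)$ —
for collapsing thresholds the radius *at the stopping time*, not $b(0)$ —
and $A_{n-1} = 2\pi^{n/2}/\Gamma(n/2)$ is the unit-sphere surface area
(`joint_density()`). The exponential factor carries no angular measure of
its own; we report densities with respect to (time × uniform surface
measure), hence the constant $1/A_{n-1}$. Written per angle *coordinates*
instead, Jacobian factors $\sin^{n-1-k}(\varphi_k)$ would appear; the
constant-vs-Jacobian choice shifts nothing in maximum-likelihood estimation
and only matters for normalization checks, which we run in the
surface-measure convention (the $n = 2$ double integral is 1 to within
$10^{-2}$ at $\Delta t = 0.01$). Averaging the factor over the sphere gives
the marginal response-time density in closed form
(`marginal_rt_density()`).

The trial-set objective (`neg_log_likelihood()`) applies a likelihood floor
of $10^{-10}$ per trial before the log — trials with $T \le 0$, beyond the
horizon, or hitting a discretization artifact contribute a large but finite
penalty, keeping the global optimizer's objective finite everywhere in the
bounds.

## Simulator

`simulate_trials()` integrates the process by Euler–Maruyama (default step
$10^{-3}$ s) with a post-step absorption check and radial projection of the
exit point onto the boundary (no bridge correction). The discrete check
overshoots: the boundary is effectively shifted outward by roughly $0.6
\sigma \sqrt{dt_\mathrm{sim}}$, so first-passage times carry a small
positive bias that shrinks as $\sqrt{dt_\mathrm{sim}}$ — the test suite
quantifies this refinement. Where a simulation serves as a *validation
oracle* against the solver (KS tolerances of 0.01–0.015), we use a finer
step ($2.5\times10^{-4}$ s) so the overshoot shift stays well inside the
tolerance; for generating fitting data the default step is ample, since
the induced bias (~2% of $b$ at worst) is far below estimation noise.
Linear-collapse simulations absorb every surviving trial at the singular
time (the boundary radius is zero there — the "fast guess" regime), and
constant-threshold trials still running at `max_time` (default 120 s) are
censored: dropped from the output with a logged count.

## Estimation and the recovery harness

`fit_hsdm()` minimizes the negative log-likelihood by differential
evolution (best/1/bin, dithered mutation factor in $[0.5, 1)$, crossover
0.7, population $\max(20, 8d)$), stopping when the population's objective
values collapse to within 0.1% relative spread, then polishing with
L-BFGS-B — the same family of routine used in the field for these
likelihoods. One first-passage grid is solved per objective evaluation and
shared across all trials; since the grid depends only on the threshold
parameters (drift enters only through the change-of-measure factor, $t_0$
only through $T = rt - t_0$), the most recent grid is cached and reused
when a proposal repeats them. Optimizer bounds default to the recovery
priors below, so estimates and generating values share a range. Fits are
deterministic given the optimizer seed.

`recovery_study()` runs the simulate-then-refit protocol: draw parameter
sets from
$$b \sim U[0.5, 6],\quad t_0 \sim U[0.1, 1],\quad \mu_i \sim U[-6, 6]$$
for constant thresholds, and
$$b_0 \sim U[2, 5],\quad \lambda \sim U[0.1, 2],\quad t_0 \sim U[0.1, 1],
\quad \mu_i \sim U[-3, 3]$$
for the linear collapse (the narrower collapse priors keep the collapse
visible in the data: strong drift ends trials before the boundary moves,
and a boundary that collapses almost immediately produces mostly fast
guesses). Each set is simulated, refit, and summarized by RMSE, Pearson
$\rho$, and $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ per parameter
(`recovery_metrics()`). Per-set seeds derive from the master seed by fixed
offsets, so reports reproduce exactly.

## Study sizes, and what the tests do and do not show

The package's acceptance checks run the recovery protocol at 40 parameter
sets per study — enough to estimate the three metrics while keeping the
default suite fast; the same studies scale to 300 sets by changing
`n_sets`. At 40 sets the $t_0$ metrics of the 50-trial study fluctuate
noticeably from seed to seed, because single unlucky draws dominate: a set
with $b$ near 6 and $\|\boldsymbol\mu\|$ near 0 has response-time spread
of several seconds, so 50 trials cannot pin $t_0$ inside its one-second
prior range, and one or two such sets can pull $R^2(t_0)$ well below its
large-$N$ level. This is estimator variance at small study size, not
solver error.

One generator detail matters specifically for collapse studies: the
simulator's overshoot acts like a boundary inflated by
$0.6\sqrt{dt_\mathrm{sim}}$, and near the shrinking radius that shift
measurably blurs the recovery of $b_0$ and $\lambda$. Collapse recovery
studies therefore simulate at $dt_\mathrm{sim} = 2.5\times10^{-4}$ s; for
constant-threshold studies the default $10^{-3}$ s leaves recovery
unaffected, the shift being a fraction of a percent of $b$.

Two qualitative results of coarse likelihood grids are worth knowing.
Non-decision time is the parameter most sensitive to $\Delta t$: at
$\Delta t = 0.2$ it is systematically overestimated (the coarse grid
smears the leading edge of the first-passage density), and the bias
disappears by $\Delta t \approx 0.05$; use $\Delta t \le 0.1$ whenever
$t_0$ matters. The threshold estimate, by contrast, shows no systematic
coarse-grid bias under this package's interpolation rule (linear between
nodes with $g(0) = 0$) — implementations with other off-grid rules can
push the threshold around as well.

What passing tests show: the solver agrees with the analytic series and
with brute-force simulation, the likelihood is a proper density, and the
full simulate-fit loop recovers generating parameters at the rates stated
above *for data generated by the model itself*. What they do not show:
robustness to contaminant trials, across-trial parameter variability,
non-uniform angular biases, or any other real-data departure from the
model — fitting real experiments still requires the usual checks.

## Worked example

```{r example}
p <- hsdm_params(n = 2, mu = c(2, 1), t0 = 0.3,
                 threshold = threshold_linear(b0 = 3, lambda = 1))
trials <- simulate_trials(p, n_trials = 500, seed = 1)
fit <- fit_hsdm(trials, "linear", delta_t = 0.02, seed = 1)
fit
```

## Limitations

Only isotropic diffusion ($\boldsymbol\sigma = \sigma I$), origin starts,
and spherically symmetric thresholds are supported; hyperelliptic
(direction-dependent) thresholds and their asymmetric collapse are out of
scope, as are across-trial variability in drift, Bayesian estimation, and
mixture/contaminant response-time models. Custom thresholds must be
strictly positive on the solved grid and supply $db/dt$; only constant and
linear thresholds are exercised by the acceptance suite.
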