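#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// First-passage density of the squared-Bessel process dY = n dt + 2 sqrt(Y) dW
// through a time-dependent squared boundary S(t), via the second-kind
// Volterra equation
//   g(t) = -2 Psi[S(t), t | y0, 0] + 2 \int_0^t g(tau) Psi[S(t), t | S(tau), tau] dtau
// discretized by the rectangle left-point scheme on a uniform grid.
//
// Kernel (Feller-type process with A = n, B = 4y):
//   Psi[S, t | y, tau] = 1/(2D) exp{-(S+y)/(2D)} (S/y)^{(n-2)/4}
//        [ (S'(t) - S/D + K(t)) I_nu(z) + z I_{n/2}(z) ],
//   z = sqrt(y S)/D,  D = t - tau,  nu = n/2 - 1,  K(t) = (n - 1 - S'(t))/2.
//
// Numerical stability: the product exp{-(S+y)/(2D)} I_nu(z) is evaluated as
// exp{-(sqrt(S)-sqrt(y))^2/(2D)} * [e^{-z} I_nu(z)] with the exponentially
// scaled modified Bessel function; the naive form overflows for small D.

// ---- fast exponentially scaled modified Bessel functions ----------------
// e^{-z} I_nu(z) for the orders the solver meets (nu = n/2 - 1 with n in
// {2, 3, 4}); other orders fall back to R's general routine. The solver
// spends nearly all its time here, and R::bessel_i allocates work arrays on
// every call.

// integer orders: Taylor series below z = 12, asymptotic expansion above
// (truncation there is ~e^{-2z} < 1e-10, far below the solver's needs)
static double scaled_int_iv(double z, int nu) {
  if (z < 12.0) {
    double term = 1.0;
    for (int j = 1; j <= nu; ++j) term *= (z / 2.0) / j;  // (z/2)^nu / nu!
    double sum = term;
    const double q = z * z / 4.0;
    for (int k = 1; k < 60; ++k) {
      term *= q / (k * (k + (double)nu));
      sum += term;
      if (term < sum * 1e-17) break;
    }
    return sum * std::exp(-z);
  }
  const double m = 4.0 * nu * nu;
  double term = 1.0, sum = 1.0;
  for (int k = 1; k < 30; ++k) {
    const double odd = 2.0 * k - 1.0;
    term *= -(m - odd * odd) / (8.0 * z * k);
    sum += term;
    if (std::fabs(term) < 1e-17 * std::fabs(sum)) break;
  }
  return sum / std::sqrt(2.0 * M_PI * z);
}

static inline double scaled_iv(double z, double nu) {
  if (z < 1e-8) {  // leading-order small-z limit, exact enough at 1e-8
    if (nu == 0.0) return 1.0 - z;
    double t = 1.0;
    for (int j = 1; j <= (int)nu; ++j) t *= (z / 2.0) / j;
    return (nu == (double)(int)nu) ? t : R::bessel_i(z, nu, 2.0);
  }
  if (nu == 0.0) return scaled_int_iv(z, 0);
  if (nu == 1.0) return scaled_int_iv(z, 1);
  if (nu == 2.0) return scaled_int_iv(z, 2);
  if (nu == 0.5)   // I_{1/2} = sqrt(2/(pi z)) sinh z
    return (1.0 - std::exp(-2.0 * z)) / (2.0 * std::sqrt(M_PI * z / 2.0));
  if (nu == 1.5) { // I_{3/2} = sqrt(2/(pi z)) (cosh z - sinh z / z)
    const double e2 = std::exp(-2.0 * z);
    const double c = (1.0 + e2) / 2.0, s = (1.0 - e2) / 2.0;
    return (c - s / z) / std::sqrt(M_PI * z / 2.0);
  }
  return R::bessel_i(z, nu, 2.0);
}

static inline double psi_point(double S, double dS, double D, double y,
                               int n, double nu) {
  const double Kt = 0.5 * (n - 1.0 - dS);
  if (y <= 0.0) {
    // y0 -> 0 limit: (S/y)^{nu/2} I_nu(z) -> (S/(2D))^nu / Gamma(nu+1),
    // and z I_{n/2}(z) -> 0
    double lg = -S / (2.0 * D) + nu * std::log(S / (2.0 * D)) -
                R::lgammafn(nu + 1.0);
    return std::exp(lg) / (2.0 * D) * (dS - S / D + Kt);
  }
  const double z = std::sqrt(y * S) / D;
  const double inu  = scaled_iv(z, nu);        // e^{-z} I_nu(z)
  const double inu1 = scaled_iv(z, nu + 1.0);  // e^{-z} I_{n/2}(z)
  const double lpref = -(std::sqrt(S) - std::sqrt(y)) * (std::sqrt(S) - std::sqrt(y)) /
                         (2.0 * D) +
                       0.5 * nu * std::log(S / y);
  const double bracket = (dS - S / D + Kt) * inu + z * inu1;
  return std::exp(lpref) * bracket / (2.0 * D);
}

// [[Rcpp::export(name = ".psi_kernel_cpp")]]
NumericVector psi_kernel_cpp(NumericVector t, NumericVector tau,
                             NumericVector y, NumericVector S_t,
                             NumericVector dS_t, int n) {
  const R_xlen_t m = t.size();
  const double nu = n / 2.0 - 1.0;
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    const double D = t[i] - tau[i];
    if (!(D > 0.0)) stop("kernel requires t > tau");
    out[i] = psi_point(S_t[i], dS_t[i], D, y[i], n, nu);
  }
  return out;
}

// Rectangle left-point solution of the Volterra equation.
// times must be i * dt, i = 1..K; S, dS are the squared boundary and its
// derivative on those times. `toeplitz` signals a constant threshold, in
// which case the kernel depends on t - tau only and is precomputed once.
// [[Rcpp::export(name = ".ie_solve_cpp")]]
NumericVector ie_solve_cpp(NumericVector times, NumericVector S,
                           NumericVector dS, int n, double dt,
                           bool toeplitz) {
  const R_xlen_t K = times.size();
  const double nu = n / 2.0 - 1.0;
  NumericVector g(K);

  // first-step terms -2 Psi[S(t_i), t_i | y0 = 0, 0]
  NumericVector base(K);
  for (R_xlen_t i = 0; i < K; ++i)
    base[i] = -2.0 * psi_point(S[i], dS[i], times[i], 0.0, n, nu);

  if (toeplitz) {
    const double Sc = S[0];
    std::vector<double> psi_d(K);  // psi_d[k-1] = Psi at lag k * dt
    for (R_xlen_t k = 1; k < K; ++k)
      psi_d[k - 1] = psi_point(Sc, 0.0, k * dt, Sc, n, nu);
    g[0] = base[0];
    for (R_xlen_t i = 1; i < K; ++i) {
      double acc = 0.0;
      for (R_xlen_t j = 0; j < i; ++j) acc += g[j] * psi_d[i - j - 1];
      g[i] = base[i] + 2.0 * dt * acc;
    }
  } else {
    g[0] = base[0];
    for (R_xlen_t i = 1; i < K; ++i) {
      const double Si = S[i], dSi = dS[i], ti = times[i];
      double acc = 0.0;
      for (R_xlen_t j = 0; j < i; ++j)
        acc += g[j] * psi_point(Si, dSi, ti - times[j], S[j], n, nu);
      g[i] = base[i] + 2.0 * dt * acc;
    }
  }
  return g;
}
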