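#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Deterministic standard-normal stream: mt19937_64 + Marsaglia polar method.
// Implemented by hand (rather than std::normal_distribution) so trajectories
// are bit-reproducible for a given seed independently of the standard
// library.
struct NormalStream {
  std::mt19937_64 eng;
  double cache;
  bool has_cache;
  explicit NormalStream(uint64_t seed) : eng(seed), cache(0), has_cache(false) {}
  double unif() {  // in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

// Euler-Maruyama integration of the coupled Stuart-Landau (Hopf normal form)
// network:
//   dx_j = [(a_j - x_j^2 - y_j^2) x_j - w_j y_j + G sum_i C_ji (x_i - x_j)
//           + F_j cos(w_j t)] dt + beta sqrt(dt) N(0,1)
//   dy_j = [(a_j - x_j^2 - y_j^2) y_j + w_j x_j + G sum_i C_ji (y_i - y_j)
//           (+ F_j cos(w_j t) if force_both)] dt + beta sqrt(dt) N(0,1)
// Independent noise draws per node and per equation. Initial state
// x, y ~ N(0, 0.1^2) drawn from the same seeded stream. The real part x_j is
// recorded every steps_per_sample steps after the transient (BOLD proxy).
// [[Rcpp::export(rng = false)]]
arma::mat hopf_integrate_cpp(const arma::vec& a,
                             const arma::vec& omega,
                             const arma::mat& C,
                             double G,
                             double beta,
                             double dt,
                             int steps_per_sample,
                             int n_samples,
                             int transient_steps,
                             double seed,
                             const arma::vec& famp,
                             bool force_both) {
  const int n = a.n_elem;
  NormalStream rng(static_cast<uint64_t>(seed));
  std::vector<double> x(n), y(n), cx(n), cy(n), xn(n), yn(n);
  for (int j = 0; j < n; ++j) x[j] = 0.1 * rng();
  for (int j = 0; j < n; ++j) y[j] = 0.1 * rng();

  const arma::vec rowsum = arma::sum(C, 1);
  arma::mat out(n_samples, n);
  const double sqdt = std::sqrt(dt);
  const long total = (long)transient_steps + (long)steps_per_sample * n_samples;
  const bool has_force = arma::any(famp != 0.0);
  const bool has_noise = beta > 0.0;
  const double* Cm = C.memptr();
  const double* ap = a.memptr();
  const double* wp = omega.memptr();
  const double* fp = famp.memptr();
  const double* rs = rowsum.memptr();
  double t = 0.0;
  int rec = 0;

  for (long step = 1; step <= total; ++step) {
    // coupling: cx_j = sum_i C(j, i) x_i (column-major walk over C)
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double xi = x[i], yi = y[i];
      const double* col = Cm + (size_t)i * n;
      for (int j = 0; j < n; ++j) {
        cx[j] += col[j] * xi;
        cy[j] += col[j] * yi;
      }
    }
    bool finite = true;
    for (int j = 0; j < n; ++j) {
      const double xj = x[j], yj = y[j];
      const double r2 = xj * xj + yj * yj;
      double dx = (ap[j] - r2) * xj - wp[j] * yj + G * (cx[j] - rs[j] * xj);
      double dy = (ap[j] - r2) * yj + wp[j] * xj + G * (cy[j] - rs[j] * yj);
      if (has_force && fp[j] != 0.0) {
        const double f = fp[j] * std::cos(wp[j] * t);
        dx += f;
        if (force_both) dy += f;
      }
      double nx = xj + dt * dx, ny = yj + dt * dy;
      if (has_noise) {
        nx += beta * sqdt * rng();
        ny += beta * sqdt * rng();
      }
      xn[j] = nx; yn[j] = ny;
      finite = finite && std::isfinite(nx) && std::isfinite(ny);
    }
    x.swap(xn); y.swap(yn);
    t += dt;
    if (!finite)
      stop("Hopf integration diverged at step %ld (t = %.1f s)", step, t);
    if (step > transient_steps &&
        (step - transient_steps) % steps_per_sample == 0) {
      for (int j = 0; j < n; ++j) out(rec, j) = x[j];
      ++rec;
    }
  }
  return out;
}

// Direct form II transposed IIR filter with initial state zi * x0scale.
// b and a are zero-padded to common length n; a[0] == 1.
static void df2t_filter(const double* b, const double* a, int n,
                        const double* x, double* y, int len,
                        const double* zi, double x0scale) {
  std::vector<double> z(n - 1);
  for (int k = 0; k < n - 1; ++k) z[k] = zi[k] * x0scale;
  for (int m = 0; m < len; ++m) {
    const double xm = x[m];
    const double ym = b[0] * xm + z[0];
    for (int k = 0; k < n - 2; ++k)
      z[k] = b[k + 1] * xm + z[k + 1] - a[k + 1] * ym;
    z[n - 2] = b[n - 1] * xm - a[n - 1] * ym;
    y[m] = ym;
  }
}

// Zero-phase forward-backward filtering with odd (reflective) end extension
// of length 3 * (n - 1) and steady-state matched initial conditions zi (as
// computed by lfilter_zi); the scheme used by the standard filtfilt
// implementations, which suppresses the edge transients that plain
// zero-state filtering produces on narrow low-frequency bands. Applied
// column-wise.
// [[Rcpp::export(rng = false)]]
arma::mat filtfilt_cpp(const arma::vec& b, const arma::vec& a,
                       const arma::vec& zi, const arma::mat& X) {
  const int T = X.n_rows, N = X.n_cols;
  const int n = std::max(b.n_elem, a.n_elem);
  arma::vec bp(n, arma::fill::zeros), ap(n, arma::fill::zeros);
  for (arma::uword i = 0; i < b.n_elem; ++i) bp(i) = b(i);
  for (arma::uword i = 0; i < a.n_elem; ++i) ap(i) = a(i);
  const int pad = 3 * (n - 1);
  if (T <= pad)
    stop("series too short for the filter: need more than %d samples", pad);
  const int L = T + 2 * pad;
  arma::mat out(T, N);
  std::vector<double> ext(L), tmp(L);
  for (int c = 0; c < N; ++c) {
    const double x0 = X(0, c), xl = X(T - 1, c);
    for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x0 - X(pad - i, c);
    for (int t = 0; t < T; ++t) ext[pad + t] = X(t, c);
    for (int i = 0; i < pad; ++i) ext[pad + T + i] = 2.0 * xl - X(T - 2 - i, c);
    df2t_filter(bp.memptr(), ap.memptr(), n, ext.data(), tmp.data(), L,
                zi.memptr(), ext[0]);
    std::reverse(tmp.begin(), tmp.end());
    df2t_filter(bp.memptr(), ap.memptr(), n, tmp.data(), ext.data(), L,
                zi.memptr(), tmp[0]);
    for (int t = 0; t < T; ++t) out(t, c) = ext[L - 1 - (pad + t)];
  }
  return out;
}
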