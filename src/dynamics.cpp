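#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Core population dynamics: per-capita growth of species i is
//   g_i = r_i - n+_i * delta - s_i x_i - sum_j c_ij x_j
//         - sum_j p-_ij x_j / (1 + h_p sum_k p+_jk x_k)   (losses to consumers)
//         + u_i / (1 + h_p u_i)                           (consumer gains, u_i = sum_k p+_ik x_k)
//         + v_i / (1 + h_m v_i)                           (mutualistic gains, v_i = sum_k m_ik x_k)
// The loss denominator saturates over the *consumer's* resources (sum over
// p+_jk), the gain denominators over the focal species' own sources.

struct Model {
  int S;
  std::vector<double> r, s;
  std::vector<double> M, Pp, Pm, C; // column-major S x S
  double delta, hp, hm;
  std::vector<int> nplus;
  std::vector<char> alive;

  double at(const std::vector<double>& A, int i, int j) const { return A[i + j * S]; }

  // n+_i = number of alive partners j with m_ij > 0 or p+_ij > 0
  void recount_nplus() {
    for (int i = 0; i < S; ++i) {
      int n = 0;
      for (int j = 0; j < S; ++j) {
        if (!alive[j] || j == i) continue;
        if (at(M, i, j) > 0.0 || at(Pp, i, j) > 0.0) ++n;
      }
      nplus[i] = n;
    }
  }

  void percapita(const std::vector<double>& x, std::vector<double>& g) const {
    std::vector<double> u(S), v(S);
    for (int i = 0; i < S; ++i) {
      double ui = 0.0, vi = 0.0;
      for (int k = 0; k < S; ++k) {
        double xk = x[k];
        if (xk == 0.0) continue;
        ui += at(Pp, i, k) * xk;
        vi += at(M, i, k) * xk;
      }
      u[i] = ui; v[i] = vi;
    }
    for (int i = 0; i < S; ++i) {
      if (!alive[i]) { g[i] = 0.0; continue; }
      double comp = 0.0, loss = 0.0;
      for (int j = 0; j < S; ++j) {
        double xj = x[j];
        if (xj == 0.0) continue;
        comp += at(C, i, j) * xj;
        double pm = at(Pm, i, j);
        if (pm > 0.0) loss += pm * xj / (1.0 + hp * u[j]);
      }
      g[i] = r[i] - nplus[i] * delta - s[i] * x[i] - comp - loss
           + u[i] / (1.0 + hp * u[i]) + v[i] / (1.0 + hm * v[i]);
    }
  }

  void deriv(const std::vector<double>& x, std::vector<double>& dx) const {
    std::vector<double> g(S);
    percapita(x, g);
    for (int i = 0; i < S; ++i) dx[i] = x[i] * g[i];
  }
};

static Model make_model(NumericVector x0, NumericVector r, NumericVector s,
                        NumericMatrix M, NumericMatrix Pp, NumericMatrix Pm,
                        NumericMatrix C, double delta, double hp, double hm) {
  Model m;
  m.S = x0.size();
  m.r.assign(r.begin(), r.end());
  m.s.assign(s.begin(), s.end());
  m.M.assign(M.begin(), M.end());
  m.Pp.assign(Pp.begin(), Pp.end());
  m.Pm.assign(Pm.begin(), Pm.end());
  m.C.assign(C.begin(), C.end());
  m.delta = delta; m.hp = hp; m.hm = hm;
  m.alive.assign(m.S, 1);
  for (int i = 0; i < m.S; ++i) if (x0[i] <= 0.0) m.alive[i] = 0;
  m.nplus.assign(m.S, 0);
  m.recount_nplus();
  return m;
}

// [[Rcpp::export]]
NumericVector rhs_percapita_cpp(NumericVector x, NumericVector r, NumericVector s,
                                NumericMatrix M, NumericMatrix Pp, NumericMatrix Pm,
                                NumericMatrix C, double delta, double hp, double hm) {
  Model m = make_model(x, r, s, M, Pp, Pm, C, delta, hp, hm);
  // user-facing RHS treats every roster member as present regardless of x
  std::fill(m.alive.begin(), m.alive.end(), 1);
  m.recount_nplus();
  std::vector<double> xv(x.begin(), x.end()), g(m.S);
  m.percapita(xv, g);
  return NumericVector(g.begin(), g.end());
}

// Dormand-Prince 4(5) adaptive step. Returns false on step-size underflow.
static bool dopri_span(const Model& m, std::vector<double>& x, double t0, double t1,
                       double rtol, double atol, double& hinit) {
  const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
  const double a21 = 1.0/5;
  const double a31 = 3.0/40, a32 = 9.0/40;
  const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
  const double a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561, a54 = -212.0/729;
  const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247, a64 = 49.0/176, a65 = -5103.0/18656;
  const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192, b5 = -2187.0/6784, b6 = 11.0/84;
  // embedded 4th order
  const double e1 = 5179.0/57600, e3 = 7571.0/16695, e4 = 393.0/640,
               e5 = -92097.0/339200, e6 = 187.0/2100, e7 = 1.0/40;
  (void)c2; (void)c3; (void)c4; (void)c5;

  int S = m.S;
  double t = t0;
  double h = hinit > 0 ? hinit : (t1 - t0) * 0.01;
  if (h > t1 - t0) h = t1 - t0;
  std::vector<double> k1(S), k2(S), k3(S), k4(S), k5(S), k6(S), k7(S), xt(S), x5(S);
  int iter_guard = 0;
  while (t < t1) {
    if (++iter_guard > 10000000) return false;
    if (h > t1 - t) h = t1 - t;
    m.deriv(x, k1);
    for (int i = 0; i < S; ++i) xt[i] = x[i] + h * a21 * k1[i];
    m.deriv(xt, k2);
    for (int i = 0; i < S; ++i) xt[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.deriv(xt, k3);
    for (int i = 0; i < S; ++i) xt[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.deriv(xt, k4);
    for (int i = 0; i < S; ++i) xt[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    m.deriv(xt, k5);
    for (int i = 0; i < S; ++i) xt[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
    m.deriv(xt, k6);
    for (int i = 0; i < S; ++i) x5[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
    m.deriv(x5, k7);
    double err = 0.0;
    for (int i = 0; i < S; ++i) {
      double x4 = x[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(x5[i]));
      double e = std::fabs(x5[i] - x4) / sc;
      if (e > err) err = e;
      if (!std::isfinite(x5[i])) err = 1e30;
    }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < S; ++i) x[i] = x5[i] < 0.0 ? 0.0 : x5[i];
    }
    double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12) return false;
  }
  hinit = h;
  return true;
}

// Integrate to ecological equilibrium: equilibrium is declared when the
// relative abundance change of every surviving species stays below rel_tol
// for eq_window consecutive steps of size eq_dt. Species falling below
// x_ext at a checkpoint are set to 0 (removed from the system: their
// partners' n+ cost counts are updated). Coarse chunks (growing 1 -> 64
// time units) are interleaved with the eq_dt windows for efficiency.
// [[Rcpp::export]]
List integrate_equilibrium_cpp(NumericVector x0, NumericVector r, NumericVector s,
                               NumericMatrix M, NumericMatrix Pp, NumericMatrix Pm,
                               NumericMatrix C, double delta, double hp, double hm,
                               double x_ext, double rel_tol, int eq_window,
                               double eq_dt, double max_time,
                               double rtol, double atol) {
  Model m = make_model(x0, r, s, M, Pp, Pm, C, delta, hp, hm);
  int S = m.S;
  std::vector<double> x(x0.begin(), x0.end());
  for (int i = 0; i < S; ++i) if (x[i] < 0.0) x[i] = 0.0;

  double t = 0.0, chunk = 1.0, h = eq_dt;
  bool converged = false;

  auto apply_extinctions = [&](void) -> bool {
    bool any = false;
    for (int i = 0; i < S; ++i) {
      if (m.alive[i] && x[i] < x_ext) { x[i] = 0.0; m.alive[i] = 0; any = true; }
    }
    if (any) m.recount_nplus();
    return any;
  };
  apply_extinctions();

  auto n_alive = [&](void) -> int {
    int n = 0;
    for (int i = 0; i < S; ++i) if (m.alive[i]) ++n;
    return n;
  };

  while (t < max_time && !converged) {
    if (n_alive() == 0) { converged = true; break; }
    // equilibrium window: eq_window consecutive eq_dt steps must all pass
    bool window_ok = true;
    std::vector<double> xprev(S);
    for (int k = 0; k < eq_window; ++k) {
      xprev = x;
      if (!dopri_span(m, x, 0.0, eq_dt, rtol, atol, h))
        stop("dynamics blow-up: step size underflow at t = %f", t);
      t += eq_dt;
      bool pruned = apply_extinctions();
      double relmax = 0.0;
      for (int i = 0; i < S; ++i) {
        if (!m.alive[i]) continue;
        double denom = std::max(xprev[i], x_ext);
        double rc = std::fabs(x[i] - xprev[i]) / denom;
        if (rc > relmax) relmax = rc;
      }
      if (pruned || relmax >= rel_tol) { window_ok = false; break; }
    }
    if (window_ok) { converged = true; break; }
    if (t >= max_time) break;
    // coarse advance
    double span = std::min(chunk, max_time - t);
    if (span > 0) {
      if (!dopri_span(m, x, 0.0, span, rtol, atol, h))
        stop("dynamics blow-up: step size underflow at t = %f", t);
      t += span;
      apply_extinctions();
    }
    if (chunk < 64.0) chunk *= 2.0;
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["t"] = t, _["converged"] = converged);
}

// Euler-Maruyama simulation around an equilibrium:
//   x_{t+dt} = x_t + x_t g(x_t) dt + sd * x_t * sqrt(dt) * Z,  Z ~ N(0,1)
// Negative excursions are clipped to 0 (0 is absorbing since both terms are
// proportional to x). Recorded values below x_ext are reported as 0 but the
// trajectory itself is not pruned. Uses R's RNG (reproducible via set.seed).
// [[Rcpp::export]]
NumericMatrix em_simulate_cpp(NumericVector x0, NumericVector r, NumericVector s,
                              NumericMatrix M, NumericMatrix Pp, NumericMatrix Pm,
                              NumericMatrix C, double delta, double hp, double hm,
                              double sd, double dt, double burn_in, double spacing,
                              int n_samples, double x_ext) {
  Model m = make_model(x0, r, s, M, Pp, Pm, C, delta, hp, hm);
  int S = m.S;
  std::vector<double> x(x0.begin(), x0.end()), g(S);
  for (int i = 0; i < S; ++i) if (x[i] < 0.0) x[i] = 0.0;
  NumericMatrix out(n_samples, S);
  double sqdt = std::sqrt(dt);
  long burn_steps = (long)std::llround(burn_in / dt);
  long gap_steps = (long)std::llround(spacing / dt);
  if (gap_steps < 1) gap_steps = 1;

  RNGScope scope;
  auto step = [&](void) {
    m.percapita(x, g);
    for (int i = 0; i < S; ++i) {
      if (x[i] == 0.0) continue;
      double noise = sd > 0.0 ? sd * x[i] * sqdt * R::norm_rand() : 0.0;
      double xn = x[i] + x[i] * g[i] * dt + noise;
      x[i] = xn < 0.0 ? 0.0 : xn;
      if (!std::isfinite(x[i])) stop("stochastic integration produced non-finite abundance; reduce dt");
    }
  };
  for (long k = 0; k < burn_steps; ++k) step();
  for (int srow = 0; srow < n_samples; ++srow) {
    for (long k = 0; k < gap_steps; ++k) step();
    for (int i = 0; i < S; ++i) out(srow, i) = x[i] >= x_ext ? x[i] : 0.0;
  }
  return out;
}
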