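// Numerical core: Sobol low-discrepancy sequence, adaptive Dormand-Prince
// RK45 integration of the growth and resistance ODE families, and the
// inner loops of the two-stage fitter (QMC global search + stochastic
// gradient descent).  Kept in C++ because the fitter evaluates the model
// O(1e4..1e6) times per mouse.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sobol sequence (unscrambled, Gray-code construction, 32-bit, Joe-Kuo
// direction numbers for dimensions up to 10; the model family needs k <= 7).
// Point 0 is the origin, matching the canonical sequence.
// ---------------------------------------------------------------------------

static const int SOBOL_MAXDIM = 10;
static const int SOBOL_BITS = 32;

// Joe-Kuo (new-joe-kuo-6) primitive polynomials and initial direction
// numbers for dimensions 2..10; dimension 1 is the van der Corput sequence.
static const int jk_s[9] = {1, 2, 3, 3, 4, 4, 5, 5, 5};
static const int jk_a[9] = {0, 1, 1, 2, 1, 4, 2, 4, 7};
static const int jk_m[9][5] = {
    {1, 0, 0, 0, 0},
    {1, 3, 0, 0, 0},
    {1, 3, 1, 0, 0},
    {1, 1, 1, 0, 0},
    {1, 1, 3, 3, 0},
    {1, 3, 5, 13, 0},
    {1, 1, 5, 5, 17},
    {1, 1, 5, 5, 5},
    {1, 1, 7, 11, 19}};

struct SobolGen {
  int dim;
  std::vector<std::array<uint32_t, SOBOL_BITS>> v;  // direction numbers
  std::vector<uint32_t> x;                          // current integer state
  uint64_t i;                                       // points emitted so far

  explicit SobolGen(int k) : dim(k), v(k), x(k, 0u), i(0) {
    if (k < 1 || k > SOBOL_MAXDIM) stop("Sobol dimension must be in 1..%d", SOBOL_MAXDIM);
    for (int d = 0; d < k; ++d) {
      if (d == 0) {
        for (int b = 0; b < SOBOL_BITS; ++b) v[d][b] = 1u << (31 - b);
      } else {
        int s = jk_s[d - 1], a = jk_a[d - 1];
        std::vector<uint32_t> m(SOBOL_BITS + 1);
        for (int t = 1; t <= s; ++t) m[t] = (uint32_t)jk_m[d - 1][t - 1];
        for (int t = s + 1; t <= SOBOL_BITS; ++t) {
          m[t] = m[t - s] ^ (m[t - s] << s);
          for (int kk = 1; kk <= s - 1; ++kk)
            m[t] ^= (((uint32_t)(a >> (s - 1 - kk)) & 1u) * m[t - kk]) << kk;
        }
        for (int b = 0; b < SOBOL_BITS; ++b) v[d][b] = m[b + 1] << (31 - b);
      }
    }
  }

  // advance to the next point (Gray-code order) and write it into out
  void next(double* out) {
    if (i == 0) {
      for (int d = 0; d < dim; ++d) out[d] = 0.0;
      ++i;
      return;
    }
    uint64_t im1 = i - 1;
    int c = 0;  // index of rightmost zero bit of i-1
    while (im1 & 1u) { im1 >>= 1; ++c; }
    for (int d = 0; d < dim; ++d) {
      x[d] ^= v[d][c];
      out[d] = (double)x[d] / 4294967296.0;
    }
    ++i;
  }
};

//' @noRd
// [[Rcpp::export(name = ".sobol_points_cpp")]]
NumericMatrix sobol_points_cpp(int n, int k, double skip) {
  SobolGen g(k);
  std::vector<double> buf(k);
  uint64_t nskip = (uint64_t)skip;
  for (uint64_t t = 0; t < nskip; ++t) g.next(buf.data());
  NumericMatrix out(n, k);
  for (int r = 0; r < n; ++r) {
    g.next(buf.data());
    for (int d = 0; d < k; ++d) out(r, d) = buf[d];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Model right-hand sides
// ---------------------------------------------------------------------------

// growth models: 1 exponential, 2 logistic, 3 allee, 4 surface, 5 von Bertalanffy
// pars layout: [r, K, m, a, b]
static inline double growth_rhs_c(int model, double V, const double* p) {
  switch (model) {
    case 1: return p[0] * V;
    case 2: return p[0] * V * (1.0 - V / p[1]);
    case 3: return p[0] * V * (1.0 - V / p[1]) * (V / p[2] - 1.0);
    // max(.,0) guards fractional powers against tiny negative overshoot
    case 4: return p[3] * V * std::pow(std::max(V + p[4], 1e-300), -1.0 / 3.0);
    case 5: return p[3] * std::pow(std::max(V, 0.0), 2.0 / 3.0) - p[4] * V;
  }
  return NA_REAL;
}

// treatment model: state (S, R, D); transition 0 none, 1 random gS, 2 drug gSD
// pars layout: [rS, rR, lS, lR, g, gamma]
static inline void treat_rhs_c(int transition, const double* y, const double* p,
                               double* dy) {
  double f = 0.0;
  if (transition == 1) f = p[4] * y[0];
  else if (transition == 2) f = p[4] * y[0] * y[2];
  dy[0] = p[0] * y[0] - f - p[2] * y[2] * y[0];
  dy[1] = p[1] * y[1] + f - p[3] * y[2] * y[1];
  dy[2] = -p[5] * y[2];
}

// ---------------------------------------------------------------------------
// Dormand-Prince RK45 with adaptive steps; integrates from t0 to t1 exactly.
// Returns false on failure (step underflow, non-finite state, blow-up).
// ---------------------------------------------------------------------------

struct OdeProblem {
  int kind;        // 1 growth (dim 1), 2 treatment (dim 3)
  int model;       // growth model id or transition code
  const double* pars;
};

static inline void ode_rhs(const OdeProblem& pr, const double* y, double* dy) {
  if (pr.kind == 1) dy[0] = growth_rhs_c(pr.model, y[0], pr.pars);
  else treat_rhs_c(pr.model, y, pr.pars, dy);
}

static bool rk45_advance(const OdeProblem& pr, int dim, double t0, double t1,
                         double* y, double rtol, double atol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  if (t1 <= t0) return true;
  double t = t0;
  double h = std::min(t1 - t0, 1.0);
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], ynew[3];
  ode_rhs(pr, y, k1);
  long iter = 0;
  const long max_iter = 100000;
  while (t < t1) {
    if (++iter > max_iter) return false;
    if (t + h > t1) h = t1 - t;
    for (int j = 0; j < dim; ++j) yt[j] = y[j] + h * a21 * k1[j];
    ode_rhs(pr, yt, k2);
    for (int j = 0; j < dim; ++j) yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    ode_rhs(pr, yt, k3);
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    ode_rhs(pr, yt, k4);
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    ode_rhs(pr, yt, k5);
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                          a64 * k4[j] + a65 * k5[j]);
    ode_rhs(pr, yt, k6);
    for (int j = 0; j < dim; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    ode_rhs(pr, ynew, k7);

    double errnorm = 0.0;
    for (int j = 0; j < dim; ++j) {
      double err = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                        e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);
    if (!std::isfinite(errnorm)) return false;

    if (errnorm <= 1.0) {  // accept
      t += h;
      for (int j = 0; j < dim; ++j) {
        y[j] = ynew[j];
        k1[j] = k7[j];  // FSAL
        if (!std::isfinite(y[j]) || std::fabs(y[j]) > 1e14) return false;
      }
    }
    double fac = errnorm > 0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12 * std::max(1.0, std::fabs(t))) return false;
  }
  (void)c2; (void)c3; (void)c4; (void)c5;
  return true;
}

// ---------------------------------------------------------------------------
// Growth model solution at requested times (integration starts at times[0]).
// ---------------------------------------------------------------------------

// pars: [r, K, m, a, b, V0]
static bool growth_solve_c(int model, const double* pars, const double* times,
                           int nt, double rtol, double atol, double* out) {
  double y = pars[5];
  OdeProblem pr{1, model, pars};
  out[0] = y;
  for (int i = 1; i < nt; ++i) {
    if (!rk45_advance(pr, 1, times[i - 1], times[i], &y, rtol, atol)) return false;
    out[i] = y;
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".growth_solve_cpp")]]
NumericVector growth_solve_cpp(int model, NumericVector pars, NumericVector times,
                               double rtol, double atol) {
  NumericVector out(times.size());
  bool ok = growth_solve_c(model, pars.begin(), times.begin(), times.size(),
                           rtol, atol, out.begin());
  if (!ok) stop("growth model integration failed");
  return out;
}

// ---------------------------------------------------------------------------
// Treatment model simulation with impulsive dosing.  Integration always
// starts at t = 0 (treatment start).  At each dose time D jumps by the dose;
// observation values at a dose time are post-jump unless pre_dose is true.
// ---------------------------------------------------------------------------

// pars: [rS, rR, lS, lR, g, gamma, S0, R0]
static bool treat_solve_c(int transition, const double* pars,
                          const double* dose_t, const double* dose_a, int nd,
                          const double* times, int nt, double rtol, double atol,
                          bool pre_dose, double* outS, double* outR,
                          double* outD) {
  double y[3] = {pars[6], pars[7], 0.0};
  OdeProblem pr{2, transition, pars};
  double t = 0.0;
  int id = 0;  // next dose index
  // apply any dose at t = 0 (post-jump state is the initial condition)
  if (!pre_dose) {
    while (id < nd && dose_t[id] <= 0.0) y[2] += dose_a[id++];
  }
  for (int i = 0; i < nt; ++i) {
    double target = times[i];
    // integrate up to target, applying intervening doses
    while (id < nd && dose_t[id] < target) {
      if (dose_t[id] > t) {
        if (!rk45_advance(pr, 3, t, dose_t[id], y, rtol, atol)) return false;
        t = dose_t[id];
      }
      y[2] += dose_a[id++];
    }
    if (target > t) {
      if (!rk45_advance(pr, 3, t, target, y, rtol, atol)) return false;
      t = target;
    }
    // dose exactly at the observation time: post-jump unless pre_dose
    if (!pre_dose) {
      while (id < nd && dose_t[id] <= target) y[2] += dose_a[id++];
    }
    outS[i] = y[0];
    outR[i] = y[1];
    outD[i] = y[2];
    if (pre_dose) {
      while (id < nd && dose_t[id] <= target) y[2] += dose_a[id++];
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".treat_solve_cpp")]]
NumericMatrix treat_solve_cpp(int transition, NumericVector pars,
                              NumericVector dose_times, NumericVector dose_amts,
                              NumericVector times, double rtol, double atol,
                              bool pre_dose) {
  int nt = times.size();
  NumericMatrix out(nt, 3);
  std::vector<double> S(nt), R(nt), D(nt);
  bool ok = treat_solve_c(transition, pars.begin(), dose_times.begin(),
                          dose_amts.begin(), dose_times.size(), times.begin(),
                          nt, rtol, atol, pre_dose, S.data(), R.data(), D.data());
  if (!ok) stop("treatment model integration failed");
  for (int i = 0; i < nt; ++i) {
    out(i, 0) = S[i];
    out(i, 1) = R[i];
    out(i, 2) = D[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fit descriptor: everything needed to map a free-parameter vector to an
// SSE against one mouse's (non-censored) observations.
//
// kind 1 = growth fit:   slots 1 r, 2 K, 3 m, 4 a, 5 b, 6 V0
// kind 2 = treatment fit: slots 1 rS, 2 rR, 3 lS, 4 lR, 5 g, 6 S0, 7 R0,
//                         8 T (profiled total initial volume; S0,R0 derived
//                         from the fixed resistance fraction)
// ---------------------------------------------------------------------------

struct FitDesc {
  int kind;
  int model;           // growth model id or transition code
  std::vector<int> slot;
  double profile_frac; // -1 when not profiling
  double gamma;
  double V0;           // observed initial volume (joint S0+R0 constraint)
  std::vector<double> dose_t, dose_a;
  std::vector<double> obs_t, obs_y;
  std::vector<double> lo, hi;
  double rtol, atol;
  bool pre_existing;   // R(0) > 0 allowed
};

static FitDesc parse_desc(const List& d) {
  FitDesc f;
  f.kind = as<int>(d["kind"]);
  f.model = as<int>(d["model"]);
  f.slot = as<std::vector<int>>(d["slot"]);
  f.profile_frac = as<double>(d["profile_frac"]);
  f.gamma = as<double>(d["gamma"]);
  f.V0 = as<double>(d["V0"]);
  f.dose_t = as<std::vector<double>>(d["dose_times"]);
  f.dose_a = as<std::vector<double>>(d["dose_amts"]);
  f.obs_t = as<std::vector<double>>(d["obs_times"]);
  f.obs_y = as<std::vector<double>>(d["obs_vols"]);
  f.lo = as<std::vector<double>>(d["lo"]);
  f.hi = as<std::vector<double>>(d["hi"]);
  f.rtol = as<double>(d["rtol"]);
  f.atol = as<double>(d["atol"]);
  f.pre_existing = as<bool>(d["pre_existing"]);
  return f;
}

// expand free vector into full parameter slots; returns false if invalid
static bool expand_params(const FitDesc& f, const double* free,
                          double* full /* size 8 */) {
  for (int j = 0; j < 8; ++j) full[j] = 0.0;
  int k = (int)f.slot.size();
  for (int j = 0; j < k; ++j) {
    if (!std::isfinite(free[j])) return false;
    full[f.slot[j] - 1] = free[j];
  }
  if (f.kind == 2 && f.profile_frac >= 0.0) {
    double T = full[7];
    full[5] = (1.0 - f.profile_frac) * T;  // S0
    full[6] = f.profile_frac * T;          // R0
  }
  return true;
}

// biological viability of a free-parameter vector under the descriptor
static bool viable_c(const FitDesc& f, const double* free) {
  double full[8];
  if (!expand_params(f, free, full)) return false;
  int k = (int)f.slot.size();
  for (int j = 0; j < k; ++j)
    if (free[j] < 0.0) return false;
  if (f.kind == 1) {
    // growth: V0 > 0; allee threshold m > 0 (RHS singular at m = 0)
    double V0 = full[5];
    if (!(V0 > 0.0)) return false;
    if (f.model == 2 || f.model == 3) {
      if (!(full[1] > 0.0)) return false;  // K > 0
    }
    if (f.model == 3 && !(full[2] > 0.0)) return false;
    return true;
  }
  // treatment: fitness cost of resistance, and total V(0) in (0, 2 V0]
  bool has_rR = false, has_lR = false;
  for (int s : f.slot) {
    if (s == 2) has_rR = true;
    if (s == 4) has_lR = true;
  }
  if (has_rR && full[0] < full[1]) return false;   // rS >= rR
  if (has_lR && !(full[2] > full[3])) return false; // lS > lR
  double tot = full[5] + full[6];
  if (!(tot > 0.0) || tot > 2.0 * f.V0) return false;
  if (!f.pre_existing && full[6] != 0.0) return false;
  return true;
}

// SSE of a free-parameter vector; +Inf if non-viable or integration fails
static double sse_c(const FitDesc& f, const double* free) {
  if (!viable_c(f, free)) return R_PosInf;
  double full[8];
  expand_params(f, free, full);
  int nt = (int)f.obs_t.size();
  double sse = 0.0;
  if (f.kind == 1) {
    // growth pars [r,K,m,a,b,V0]; note integration starts at first obs time
    std::vector<double> pred(nt);
    if (!growth_solve_c(f.model, full, f.obs_t.data(), nt, f.rtol, f.atol,
                        pred.data()))
      return R_PosInf;
    for (int i = 0; i < nt; ++i) {
      double d = f.obs_y[i] - pred[i];
      sse += d * d;
    }
  } else {
    // treatment pars [rS,rR,lS,lR,g,gamma,S0,R0]
    double pars[8] = {full[0], full[1], full[2], full[3], full[4],
                      f.gamma, full[5], full[6]};
    std::vector<double> S(nt), R(nt), D(nt);
    if (!treat_solve_c(f.model, pars, f.dose_t.data(), f.dose_a.data(),
                       (int)f.dose_t.size(), f.obs_t.data(), nt, f.rtol,
                       f.atol, false, S.data(), R.data(), D.data()))
      return R_PosInf;
    for (int i = 0; i < nt; ++i) {
      double d = f.obs_y[i] - (S[i] + R[i]);
      sse += d * d;
    }
  }
  return sse;
}

//' @noRd
// [[Rcpp::export(name = ".sse_eval_cpp")]]
double sse_eval_cpp(List desc, NumericVector free) {
  FitDesc f = parse_desc(desc);
  if ((int)f.slot.size() != free.size()) stop("free parameter length mismatch");
  return sse_c(f, free.begin());
}

//' @noRd
// [[Rcpp::export(name = ".viable_eval_cpp")]]
bool viable_eval_cpp(List desc, NumericVector free) {
  FitDesc f = parse_desc(desc);
  if ((int)f.slot.size() != free.size()) stop("free parameter length mismatch");
  return viable_c(f, free.begin());
}

// ---------------------------------------------------------------------------
// Stage 1: Sobol QMC search.  Points are scaled affinely into [lo, hi],
// non-viable sets discarded, and the minimum-SSE set returned.
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".qmc_search_cpp")]]
List qmc_search_cpp(List desc, double n_points, double skip) {
  FitDesc f = parse_desc(desc);
  int k = (int)f.slot.size();
  SobolGen g(k);
  std::vector<double> u(k), p(k), best(k);
  uint64_t nskip = (uint64_t)skip, n = (uint64_t)n_points;
  for (uint64_t t = 0; t < nskip; ++t) g.next(u.data());
  double best_sse = R_PosInf;
  long n_viable = 0;
  bool have = false;
  for (uint64_t t = 0; t < n; ++t) {
    g.next(u.data());
    for (int j = 0; j < k; ++j) p[j] = f.lo[j] + u[j] * (f.hi[j] - f.lo[j]);
    if (!viable_c(f, p.data())) continue;
    ++n_viable;
    double s = sse_c(f, p.data());
    if (s < best_sse) {
      best_sse = s;
      best = p;
      have = true;
    }
    if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["best"] = have ? wrap(best) : R_NilValue,
                      _["sse"] = best_sse, _["n_viable"] = (double)n_viable);
}

// ---------------------------------------------------------------------------
// Stage 2: stochastic gradient descent.  Every parameter is perturbed by a
// uniform draw from [-10^(a-1), 10^(a-1)] where a = floor(log10 |p|)
// (a = -3 at p = 0); moves that are non-viable or increase the SSE are
// rejected.  Uses R's RNG so results are reproducible under set.seed().
// ---------------------------------------------------------------------------

static inline double perturb_halfwidth(double p) {
  if (p == 0.0) return 1e-4;
  int a = (int)std::floor(std::log10(std::fabs(p)));
  return std::pow(10.0, a - 1);
}

//' @noRd
// [[Rcpp::export(name = ".grad_descent_cpp")]]
List grad_descent_cpp(List desc, NumericVector start, double n_iter,
                      int trace_every) {
  FitDesc f = parse_desc(desc);
  int k = (int)f.slot.size();
  if (k != start.size()) stop("start length mismatch");
  std::vector<double> cur(start.begin(), start.end()), prop(k);
  double cur_sse = sse_c(f, cur.data());
  long n = (long)n_iter;
  std::vector<double> trace;
  if (trace_every > 0) trace.reserve(n / trace_every + 2);
  if (trace_every > 0) trace.push_back(cur_sse);
  RNGScope scope;
  long accepted = 0;
  for (long t = 0; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double w = perturb_halfwidth(cur[j]);
      prop[j] = cur[j] + R::runif(-w, w);
    }
    if (viable_c(f, prop.data())) {
      double s = sse_c(f, prop.data());
      if (s <= cur_sse) {
        cur = prop;
        cur_sse = s;
        ++accepted;
      }
    }
    if (trace_every > 0 && ((t + 1) % trace_every == 0)) trace.push_back(cur_sse);
    if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = wrap(cur), _["sse"] = cur_sse,
                      _["accepted"] = (double)accepted,
                      _["trace"] = wrap(trace));
}
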