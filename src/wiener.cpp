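#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wiener first-passage-time density (two absorbing boundaries, diffusion SD
// s = 1). Infinite-series solutions in scaled time u = t / a^2 with relative
// start w = z / a; small-time and large-time representations with the
// standard error-bound rule for the number of terms, absolute tolerance EPS.
// ---------------------------------------------------------------------------

static const double EPS_SERIES = 1e-10;

// scaled lower-boundary density at drift 0, boundary 1, start w
static double wfpt_scaled(double u, double w, int method) {
  // method: 0 = auto, 1 = small-time, 2 = large-time
  if (u <= 0.0) return 0.0;
  // terms needed for tolerance EPS_SERIES
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * EPS_SERIES < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u *
                         std::log(2.0 * EPS_SERIES * std::sqrt(2.0 * M_PI * u)));
    double lo = std::sqrt(u) + 1.0;
    if (ks < lo) ks = lo;
  } else {
    ks = 2.0;
  }
  if (M_PI * u * EPS_SERIES < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * EPS_SERIES) / (M_PI * M_PI * u));
    double lo = 1.0 / (M_PI * std::sqrt(u));
    if (kl < lo) kl = lo;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }
  bool use_small = (method == 1) || (method == 0 && ks < kl);
  double f = 0.0;
  if (use_small) {
    // sum_{k=-K}^{K} x_k exp(-x_k^2 / 2u), x_k = w + 2k, via multiplicative
    // recurrences on the quadratic exponents (two exp calls per direction)
    int K = (int)std::ceil(ks);
    double inv2u = 1.0 / (2.0 * u);
    double e8 = std::exp(-8.0 * inv2u);
    double x = w;
    double E = std::exp(-x * x * inv2u);
    double g = std::exp(-(4.0 * x + 4.0) * inv2u);
    for (int k = 0; k <= K; ++k) {
      f += x * E;
      E *= g; g *= e8; x += 2.0;
    }
    x = w - 2.0;
    E = std::exp(-x * x * inv2u);
    g = std::exp(-(-4.0 * x + 4.0) * inv2u);
    for (int k = 1; k <= K; ++k) {
      f += x * E;
      E *= g; g *= e8; x -= 2.0;
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    // sum_k k exp(-k^2 pi^2 u / 2) sin(k pi w); geometric recurrence for the
    // exponentials, Chebyshev recurrence for the sines
    int K = (int)std::ceil(kl);
    double c = M_PI * M_PI * u / 2.0;
    double q = std::exp(-c);
    double q2 = q * q;
    double e = q;
    double r = q * q2;
    double s0 = 0.0, s1 = std::sin(M_PI * w);
    double two_cos = 2.0 * std::cos(M_PI * w);
    for (int k = 1; k <= K; ++k) {
      f += k * e * s1;
      e *= r; r *= q2;
      double s2 = two_cos * s1 - s0;
      s0 = s1; s1 = s2;
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// defective FPT density at boundary (upper = true/false), start z_rel, drift v
static inline double wfpt_density_1(double t, double a, double z_rel, double v,
                                    bool upper, int method) {
  if (t <= 0.0) return 0.0;
  double w = upper ? 1.0 - z_rel : z_rel;
  double vv = upper ? -v : v;
  double u = t / (a * a);
  double mult = std::exp(-vv * a * w - vv * vv * t / 2.0) / (a * a);
  return mult * wfpt_scaled(u, w, method);
}

// P(absorbed at upper boundary), closed form
static inline double absorb_upper(double a, double z_rel, double v) {
  double z = z_rel * a;
  if (std::fabs(v) < 1e-10) return z_rel;
  // (1 - exp(-2 v z)) / (1 - exp(-2 v a))
  return std::expm1(-2.0 * v * z) / std::expm1(-2.0 * v * a);
}

// defective CDF at one boundary: P_boundary minus the large-time tail series
// integrated term by term
static double wfpt_cdf_1(double t, double a, double z_rel, double v,
                         bool upper) {
  if (t <= 0.0) return 0.0;
  double w = upper ? 1.0 - z_rel : z_rel;
  double vv = upper ? -v : v;
  double P = upper ? absorb_upper(a, z_rel, v) : 1.0 - absorb_upper(a, z_rel, v);
  double pref = (M_PI / (a * a)) * std::exp(-vv * a * w - vv * vv * t / 2.0);
  double c = M_PI * M_PI * t / (2.0 * a * a);
  double lam0 = vv * vv / 2.0;
  double lamc = M_PI * M_PI / (2.0 * a * a);
  double q = std::exp(-c);
  double q2 = q * q;
  double e = q;      // exp(-k^2 c), k = 1
  double r = q * q2;
  double s0 = 0.0, s1 = std::sin(M_PI * w);
  double two_cos = 2.0 * std::cos(M_PI * w);
  double tail = 0.0;
  int stable = 0;
  for (int k = 1; k <= 100000; ++k) {
    double term = k * s1 * e / (lam0 + k * k * lamc);
    tail += term;
    e *= r; r *= q2;
    double s2 = two_cos * s1 - s0;
    s0 = s1; s1 = s2;
    if (std::fabs(term) < 1e-14 * (1.0 + std::fabs(tail))) {
      if (++stable >= 3) break;
    } else {
      stable = 0;
    }
  }
  double F = P - pref * tail;
  if (F < 0.0) F = 0.0;
  if (F > P) F = P;
  return F;
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double a, double z_rel,
                               double v, bool upper, int method) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_density_1(t[i], a, z_rel, v, upper, method);
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_cdf_cpp(NumericVector t, double a, double z_rel, double v,
                           bool upper) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_cdf_1(t[i], a, z_rel, v, upper);
  return out;
}

// [[Rcpp::export]]
double absorb_upper_cpp(double a, double z_rel, double v) {
  return absorb_upper(a, z_rel, v);
}

// Total DDM log-likelihood. Responded trials: rt, is_upper (1 = matching
// boundary), cond (0-based condition index into v). Omissions enter as
// per-condition counts. Nondecision time t0 ~ U(Ter - st0/2, Ter + st0/2)
// integrated by Gauss-Legendre nodes gl_x (on [-1, 1]) with weights gl_w.
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector is_upper,
                      IntegerVector cond, IntegerVector n_omit,
                      NumericVector v, double a, double z_rel, double Ter,
                      double st0, double p_gf, double window,
                      NumericVector gl_x, NumericVector gl_w) {
  int n = rt.size();
  int nq = (st0 < 1e-10) ? 1 : gl_x.size();
  std::vector<double> t0s(nq), wts(nq);
  if (nq == 1) {
    t0s[0] = Ter;
    wts[0] = 1.0;
  } else {
    for (int j = 0; j < nq; ++j) {
      t0s[j] = Ter + st0 * gl_x[j] / 2.0;
      wts[j] = gl_w[j] / 2.0;
    }
  }
  double total = 0.0;
  double log_go = log1p(-p_gf);
  int nc = v.size();
  double a2 = a * a;
  // hoist the drift-dependent exponential factors: per (condition, boundary)
  // base exp(-vv a w)/a^2 and per-node exp(+vv^2 t0_j / 2), so each
  // trial-node evaluation only needs the series itself
  std::vector<double> base(nc * 2), wcol(nc * 2), vvcol(nc * 2);
  std::vector<double> nodef(nc * 2 * nq);
  for (int c = 0; c < nc; ++c) {
    for (int upi = 0; upi < 2; ++upi) {
      double w = upi ? 1.0 - z_rel : z_rel;
      double vv = upi ? -v[c] : v[c];
      int idx = c * 2 + upi;
      wcol[idx] = w;
      vvcol[idx] = vv;
      base[idx] = std::exp(-vv * a * w) / a2;
      for (int j = 0; j < nq; ++j)
        nodef[idx * nq + j] = wts[j] * std::exp(vv * vv * t0s[j] / 2.0);
    }
  }
  for (int i = 0; i < n; ++i) {
    int idx = cond[i] * 2 + (is_upper[i] == 1 ? 1 : 0);
    double vv = vvcol[idx];
    double w = wcol[idx];
    double D = std::exp(-vv * vv * rt[i] / 2.0);
    double series = 0.0;
    for (int j = 0; j < nq; ++j) {
      double t = rt[i] - t0s[j];
      if (t > 0.0)
        series += nodef[idx * nq + j] * wfpt_scaled(t / a2, w, 0);
    }
    double dens = base[idx] * D * series;
    if (dens <= 0.0) return R_NegInf;
    total += log_go + std::log(dens);
  }
  for (int c = 0; c < nc; ++c) {
    if (n_omit[c] == 0) continue;
    double surv = 0.0;
    for (int j = 0; j < nq; ++j) {
      double tau = window - t0s[j];
      double crossed = 0.0;
      if (tau > 0.0)
        crossed = wfpt_cdf_1(tau, a, z_rel, v[c], true) +
          wfpt_cdf_1(tau, a, z_rel, v[c], false);
      double s = 1.0 - crossed;
      if (s < 0.0) s = 0.0;
      surv += wts[j] * s;
    }
    double p_om = p_gf + (1.0 - p_gf) * surv;
    if (p_om <= 0.0) return R_NegInf;
    total += n_omit[c] * std::log(p_om);
  }
  return total;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama path simulator. Uses an internal xoshiro256++ stream
// (seeded deterministically from the `seed` argument) because path
// simulation at small dt needs billions of normal draws.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {  // Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// Simulate n first passages from start z between 0 and a with drift v.
// Returns decision times and boundary codes (1 upper, 0 lower, -1 time cap).
// [[Rcpp::export]]
List ddm_euler_cpp(int n, double v, double a, double z, double dt,
                   double tmax, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector time(n);
  IntegerVector boundary(n);
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil(tmax / dt);
  for (int i = 0; i < n; ++i) {
    double x = z;
    int step = 0;
    int b = -1;
    while (step < max_steps) {
      ++step;
      x += v * dt + sdt * rng.norm();
      if (x >= a) { b = 1; break; }
      if (x <= 0.0) { b = 0; break; }
    }
    time[i] = step * dt;
    boundary[i] = b;
  }
  return List::create(_["time"] = time, _["boundary"] = boundary);
}
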