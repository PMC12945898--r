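#include <Rcpp.h>
using namespace Rcpp;

// Single-accumulator LBA finishing-time density: start ~ U(0, A),
// rate ~ N(v, sv) (negative draws never finish), threshold b.
static inline double node_density(double t, double b, double A, double v,
                                  double sv) {
  if (t <= 0.0) return 0.0;
  if (A < 1e-6) {
    double z = (b / t - v) / sv;
    return (b / (t * t)) * R::dnorm(z, 0.0, 1.0, 0) / sv;
  }
  double ts = t * sv;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double d = (-v * R::pnorm(z1, 0.0, 1.0, 1, 0) + sv * R::dnorm(z1, 0.0, 1.0, 0)
              + v * R::pnorm(z2, 0.0, 1.0, 1, 0) - sv * R::dnorm(z2, 0.0, 1.0, 0)) / A;
  return d > 0.0 ? d : 0.0;
}

static inline double node_cdf(double t, double b, double A, double v,
                              double sv) {
  if (t <= 0.0) return 0.0;
  double p;
  if (A < 1e-6) {
    p = R::pnorm((v - b / t) / sv, 0.0, 1.0, 1, 0);
  } else {
    double ts = t * sv;
    double z1 = (b - A - t * v) / ts;
    double z2 = (b - t * v) / ts;
    p = 1.0 + ((b - A - t * v) / A) * R::pnorm(z1, 0.0, 1.0, 1, 0)
      - ((b - t * v) / A) * R::pnorm(z2, 0.0, 1.0, 1, 0)
      + (ts / A) * (R::dnorm(z1, 0.0, 1.0, 0) - R::dnorm(z2, 0.0, 1.0, 0));
  }
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// Full LBA log-likelihood: responded trials indexed by condition and whether
// the winning accumulator matches the stimulus; omissions as per-condition
// counts with the closed-form omission probability.
// [[Rcpp::export]]
double lba_loglik_full_cpp(NumericVector rt, IntegerVector win_is_match,
                           IntegerVector cond, IntegerVector n_omit,
                           NumericVector v_match, NumericVector v_mismatch,
                           NumericVector b_match, NumericVector b_mismatch,
                           double A, double sv_match, double sv_mismatch,
                           double t0, double p_gf, double window) {
  int n = rt.size();
  double total = 0.0;
  double log_go = log1p(-p_gf);
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - t0;
    if (t <= 0.0) return R_NegInf;
    int c = cond[i];
    double f, s;
    if (win_is_match[i] == 1) {
      f = node_density(t, b_match[c], A, v_match[c], sv_match);
      s = 1.0 - node_cdf(t, b_mismatch[c], A, v_mismatch[c], sv_mismatch);
    } else {
      f = node_density(t, b_mismatch[c], A, v_mismatch[c], sv_mismatch);
      s = 1.0 - node_cdf(t, b_match[c], A, v_match[c], sv_match);
    }
    double lik = f * s;
    if (lik <= 0.0) return R_NegInf;
    total += log_go + log(lik);
  }
  int nc = v_match.size();
  double tau = window - t0;
  for (int c = 0; c < nc; ++c) {
    if (n_omit[c] == 0) continue;
    double surv = (1.0 - node_cdf(tau, b_match[c], A, v_match[c], sv_match)) *
      (1.0 - node_cdf(tau, b_mismatch[c], A, v_mismatch[c], sv_mismatch));
    double p_om = p_gf + (1.0 - p_gf) * surv;
    if (p_om <= 0.0) return R_NegInf;
    total += n_omit[c] * std::log(p_om);
  }
  return total;
}
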