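#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise belief filters. These sit inside the MAP objective and are
// called tens of thousands of times per subject fit, hence C++.
//
// Each core returns a List of per-trial vectors plus an `invalid` trial
// index (0 when the whole trajectory is numerically valid; 1-based
// otherwise). The R wrappers turn `invalid` into a classed condition so
// the fitting layer can treat the parameter point as -Inf.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Three-level hierarchical Gaussian filter for binary inputs.
// State carried across trials: (mu2, sigma2, mu3, sigma3).
// [[Rcpp::export(name = ".hgf3_core")]]
List hgf3_core(IntegerVector u, double omega2, double omega3, double kappa,
               double mu2_0, double sigma2_0, double mu3_0, double sigma3_0) {
  int n = u.size();
  NumericVector muhat1(n), delta1(n), mu2(n), sigma2(n), mu3(n), sigma3(n),
      alpha2(n), alpha3(n), surprise(n), unc1(n), unc2(n), volatility(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  int invalid = 0;

  for (int t = 0; t < n; ++t) {
    double mh1 = logistic(m2);
    double d1 = u[t] - mh1;
    double v2 = std::exp(kappa * m3 + omega2);
    double pihat2 = 1.0 / (s2 + v2);
    double pi2 = pihat2 + mh1 * (1.0 - mh1);
    double a2 = 1.0 / pi2;
    double m2_new = m2 + a2 * d1;
    double s2_new = 1.0 / pi2;
    double w2 = v2 * pihat2;
    double d2 = (s2_new + (m2_new - m2) * (m2_new - m2)) * pihat2 - 1.0;
    double pihat3 = 1.0 / (s3 + std::exp(omega3));
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(pi3 > 0.0) || !R_finite(pi3)) { invalid = t + 1; break; }
    double a3 = 0.5 * kappa * w2 / pi3;
    double m3_new = m3 + a3 * d2;
    double s3_new = 1.0 / pi3;
    if (!R_finite(m2_new) || !R_finite(s2_new) || !R_finite(m3_new) ||
        !R_finite(s3_new) || !(s2_new > 0.0) || !(s3_new > 0.0)) {
      invalid = t + 1; break;
    }

    muhat1[t] = mh1;
    delta1[t] = d1;
    surprise[t] = -std::log(u[t] == 1 ? mh1 : 1.0 - mh1);
    unc1[t] = mh1 * (1.0 - mh1);
    unc2[t] = s2 + v2;            // 1 / pihat2, prediction-time
    volatility[t] = std::exp(m3); // prediction-time phasic volatility
    // learning rate of the outcome-probability belief muhat1 (the
    // mu2-space update gain a2 = 1/pi2 equals sigma2' and is exposed there)
    alpha2[t] = mh1 * (1.0 - mh1) * a2;
    alpha3[t] = a3;
    mu2[t] = m2_new; sigma2[t] = s2_new;
    mu3[t] = m3_new; sigma3[t] = s3_new;

    m2 = m2_new; s2 = s2_new; m3 = m3_new; s3 = s3_new;
  }

  return List::create(
      _["muhat1"] = muhat1, _["delta1"] = delta1, _["surprise"] = surprise,
      _["unc1"] = unc1, _["unc2"] = unc2, _["volatility"] = volatility,
      _["mu2"] = mu2, _["sigma2"] = sigma2, _["alpha2"] = alpha2,
      _["mu3"] = mu3, _["sigma3"] = sigma3, _["alpha3"] = alpha3,
      _["invalid"] = invalid);
}

// Two-level HGF: volatility updates eliminated, v2 = exp(omega2) constant.
// [[Rcpp::export(name = ".hgf2_core")]]
List hgf2_core(IntegerVector u, double omega2, double mu2_0, double sigma2_0) {
  int n = u.size();
  NumericVector muhat1(n), delta1(n), mu2(n), sigma2(n), alpha2(n),
      surprise(n), unc1(n), unc2(n);
  double m2 = mu2_0, s2 = sigma2_0;
  double v2 = std::exp(omega2);
  int invalid = 0;

  for (int t = 0; t < n; ++t) {
    double mh1 = logistic(m2);
    double d1 = u[t] - mh1;
    double pihat2 = 1.0 / (s2 + v2);
    double pi2 = pihat2 + mh1 * (1.0 - mh1);
    double a2 = 1.0 / pi2;
    double m2_new = m2 + a2 * d1;
    double s2_new = 1.0 / pi2;
    if (!R_finite(m2_new) || !R_finite(s2_new) || !(s2_new > 0.0)) {
      invalid = t + 1; break;
    }

    muhat1[t] = mh1;
    delta1[t] = d1;
    surprise[t] = -std::log(u[t] == 1 ? mh1 : 1.0 - mh1);
    unc1[t] = mh1 * (1.0 - mh1);
    unc2[t] = s2 + v2;
    alpha2[t] = mh1 * (1.0 - mh1) * a2;  // probability-space learning rate
    mu2[t] = m2_new; sigma2[t] = s2_new;

    m2 = m2_new; s2 = s2_new;
  }

  return List::create(
      _["muhat1"] = muhat1, _["delta1"] = delta1, _["surprise"] = surprise,
      _["unc1"] = unc1, _["unc2"] = unc2, _["mu2"] = mu2,
      _["sigma2"] = sigma2, _["alpha2"] = alpha2, _["invalid"] = invalid);
}

// Rescorla-Wagner delta rule with fixed learning rate.
// [[Rcpp::export(name = ".rw_core")]]
List rw_core(IntegerVector u, double alpha_rw, double v0) {
  int n = u.size();
  NumericVector muhat1(n), delta1(n), surprise(n), unc1(n);
  double v = v0;
  for (int t = 0; t < n; ++t) {
    muhat1[t] = v;
    delta1[t] = u[t] - v;
    surprise[t] = -std::log(u[t] == 1 ? v : 1.0 - v);
    unc1[t] = v * (1.0 - v);
    v = v + alpha_rw * delta1[t];
  }
  return List::create(_["muhat1"] = muhat1, _["delta1"] = delta1,
                      _["surprise"] = surprise, _["unc1"] = unc1,
                      _["invalid"] = 0);
}

// Sutton K1: scalar meta-learning of the gain, exponentiated and capped at 1.
// [[Rcpp::export(name = ".sk1_core")]]
List sk1_core(IntegerVector u, double mu_meta, double v0, double b0, double h0,
              double eps) {
  int n = u.size();
  NumericVector muhat1(n), delta1(n), surprise(n), unc1(n), lr(n);
  double v = v0, b = b0, h = h0;
  int invalid = 0;
  for (int t = 0; t < n; ++t) {
    muhat1[t] = v;
    double d = u[t] - v;
    delta1[t] = d;
    surprise[t] = -std::log(u[t] == 1 ? v : 1.0 - v);
    unc1[t] = v * (1.0 - v);
    b = b + mu_meta * d * h;
    double k = std::exp(b);
    if (k > 1.0) k = 1.0;
    lr[t] = k;
    v = v + k * d;
    if (v < eps) v = eps;
    if (v > 1.0 - eps) v = 1.0 - eps;
    h = h * std::max(0.0, 1.0 - k) + k * d;
    if (!R_finite(v) || !R_finite(b) || !R_finite(h)) { invalid = t + 1; break; }
  }
  return List::create(_["muhat1"] = muhat1, _["delta1"] = delta1,
                      _["surprise"] = surprise, _["unc1"] = unc1,
                      _["lr"] = lr, _["invalid"] = invalid);
}
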