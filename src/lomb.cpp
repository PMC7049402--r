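#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

// Lomb-Scargle periodogram of a mean-centred, unevenly sampled signal on a
// uniform frequency grid f_k = f0 + k * df, k = 0..nf-1. The per-sample phase
// factors are advanced across the grid by complex recurrence (two multiplies
// per frequency instead of four trig calls), re-synchronised from trig every
// 1024 steps to keep rounding drift negligible.
//
// Classic tau-corrected form:
//   P(w) = 0.5 * [ (sum y cos w(t-tau))^2 / sum cos^2 w(t-tau)
//                + (sum y sin w(t-tau))^2 / sum sin^2 w(t-tau) ]
// with tan(2 w tau) = sum sin(2wt) / sum cos(2wt).

//' @noRd
// [[Rcpp::export(name = ".lomb_power")]]
NumericVector lomb_power(NumericVector t, NumericVector y,
                         double f0, double df, int nf) {
  int n = t.size();
  NumericVector CS(nf), SS(nf), C2(nf), S2(nf);
  const double TWO_PI = 2.0 * M_PI;
  for (int j = 0; j < n; ++j) {
    double tj = t[j], yj = y[j];
    std::complex<double> z = std::polar(1.0, TWO_PI * df * tj);
    std::complex<double> w = std::polar(1.0, TWO_PI * f0 * tj);
    for (int k = 0; k < nf; ++k) {
      if ((k & 1023) == 1023)
        w = std::polar(1.0, TWO_PI * (f0 + (k + 1) * df) * tj);
      double c = w.real(), s = w.imag();
      CS[k] += yj * c;
      SS[k] += yj * s;
      C2[k] += c * c - s * s;   // cos(2wt)
      S2[k] += 2.0 * c * s;     // sin(2wt)
      if ((k & 1023) != 1023) w *= z;
    }
  }
  NumericVector P(nf);
  for (int k = 0; k < nf; ++k) {
    double twt = std::atan2(S2[k], C2[k]);   // 2 w tau
    double ct = std::cos(0.5 * twt), st = std::sin(0.5 * twt);
    double yc = CS[k] * ct + SS[k] * st;
    double ys = SS[k] * ct - CS[k] * st;
    // sum cos^2 w(t-tau) = n/2 + 0.5*(C2*cos(2wtau) + S2*sin(2wtau))
    double c2t = std::cos(twt), s2t = std::sin(twt);
    double cc = 0.5 * n + 0.5 * (C2[k] * c2t + S2[k] * s2t);
    double ss = 0.5 * n - 0.5 * (C2[k] * c2t + S2[k] * s2t);
    double p = 0.0;
    if (cc > 0) p += yc * yc / cc;
    if (ss > 0) p += ys * ys / ss;
    P[k] = 0.5 * p;
  }
  return P;
}
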