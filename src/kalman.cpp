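#include <Rcpp.h>
using namespace Rcpp;

// Sequential exact-likelihood filters for stationary Gaussian movement
// models observed with an error nugget at irregular times. Time in hours,
// coordinates in metres. Both axes share the covariance recursion.

// [[Rcpp::export(name = ".ou_filter_cpp")]]
double ou_filter(NumericVector t, NumericVector x, NumericVector y,
                 double mux, double muy, double sigma2, double tau,
                 double R) {
  const int n = t.size();
  double mx = 0.0, my = 0.0, P = sigma2, ll = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double phi = std::exp(-(t[i] - t[i - 1]) / tau);
      mx *= phi;
      my *= phi;
      P = phi * phi * P + sigma2 * (1.0 - phi * phi);
    }
    double S = P + R;
    double vx = x[i] - mux - mx;
    double vy = y[i] - muy - my;
    ll += -0.5 * (2.0 * (log2pi + std::log(S)) + (vx * vx + vy * vy) / S);
    double K = P / S;
    mx += K * vx;
    my += K * vy;
    P *= (1.0 - K);
  }
  return ll;
}

// OUF: state (position - mu, velocity) per axis, shared 2x2 covariance.
// Transition exp(A d) with A = [[0,1],[-l1 l2, -(l1+l2)]], eigenvalues
// -l1 = -1/tau_pos and -l2 = -1/tau_vel (distinct).
// [[Rcpp::export(name = ".ouf_filter_cpp")]]
double ouf_filter(NumericVector t, NumericVector x, NumericVector y,
                  double mux, double muy, double sigma2, double tau_pos,
                  double tau_vel, double R) {
  const int n = t.size();
  const double l1 = 1.0 / tau_pos, l2 = 1.0 / tau_vel;
  const double Pi00 = sigma2, Pi11 = sigma2 * l1 * l2;
  // state means per axis and shared covariance
  double mx0 = 0.0, mx1 = 0.0, my0 = 0.0, my1 = 0.0;
  double P00 = Pi00, P01 = 0.0, P11 = Pi11;
  double ll = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double d = t[i] - t[i - 1];
      double e1 = std::exp(-l1 * d), e2 = std::exp(-l2 * d);
      double den = l2 - l1;
      // Phi = (e1 (A + l2 I) - e2 (A + l1 I)) / (l2 - l1)
      double F00 = (e1 * l2 - e2 * l1) / den;
      double F01 = (e1 - e2) / den;
      double F10 = -l1 * l2 * F01;
      double F11 = (e2 * l2 - e1 * l1) / den;
      // mean propagation per axis
      double nx0 = F00 * mx0 + F01 * mx1, nx1 = F10 * mx0 + F11 * mx1;
      double ny0 = F00 * my0 + F01 * my1, ny1 = F10 * my0 + F11 * my1;
      mx0 = nx0; mx1 = nx1; my0 = ny0; my1 = ny1;
      // P <- F P F' + (Pi - F Pi F')
      double A00 = F00 * P00 + F01 * P01, A01 = F00 * P01 + F01 * P11;
      double A10 = F10 * P00 + F11 * P01, A11 = F10 * P01 + F11 * P11;
      double FP00 = A00 * F00 + A01 * F01;
      double FP01 = A00 * F10 + A01 * F11;
      double FP11 = A10 * F10 + A11 * F11;
      // F Pi F' (Pi diagonal)
      double G00 = F00 * F00 * Pi00 + F01 * F01 * Pi11;
      double G01 = F00 * F10 * Pi00 + F01 * F11 * Pi11;
      double G11 = F10 * F10 * Pi00 + F11 * F11 * Pi11;
      P00 = FP00 + (Pi00 - G00);
      P01 = FP01 + (0.0 - G01);
      P11 = FP11 + (Pi11 - G11);
    }
    double S = P00 + R;
    double vx = x[i] - mux - mx0;
    double vy = y[i] - muy - my0;
    ll += -0.5 * (2.0 * (log2pi + std::log(S)) + (vx * vx + vy * vy) / S);
    double K0 = P00 / S, K1 = P01 / S;
    mx0 += K0 * vx; mx1 += K1 * vx;
    my0 += K0 * vy; my1 += K1 * vy;
    // P <- P - K (P00, P01)
    double nP00 = P00 - K0 * P00;
    double nP01 = P01 - K0 * P01;
    double nP11 = P11 - K1 * P01;
    P00 = nP00; P01 = nP01; P11 = nP11;
  }
  return ll;
}
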