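// Fixed-step RK4 cores for the four heartbeat models. Delayed coupling terms
// are evaluated from the trajectory being built, at a fixed sample offset
// round(tau / h), and are held frozen across the four stages of each step
// (start-of-step lookup). Pre-history (t < t0) is the constant initial state.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool row_finite(const double* s, int d) {
  for (int k = 0; k < d; ++k)
    if (!std::isfinite(s[k])) return false;
  return true;
}

// generic RK4 driver: Deriv is callable(i, t, const double* s, double* ds)
// where i is the current step index (delay lookups use it, frozen per step).
template <typename Deriv>
static List rk4_drive(Deriv deriv, NumericVector y0, double h, int n, int d) {
  NumericMatrix out(n + 1, d);
  std::vector<double> s(d), k1(d), k2(d), k3(d), k4(d), tmp(d);
  for (int k = 0; k < d; ++k) {
    s[k] = y0[k];
    out(0, k) = s[k];
  }
  bool ok = true;
  int i_fail = -1;
  for (int i = 0; i < n; ++i) {
    double t = i * h;
    deriv(i, t, s.data(), k1.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k1[k];
    deriv(i, t + 0.5 * h, tmp.data(), k2.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k2[k];
    deriv(i, t + 0.5 * h, tmp.data(), k3.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + h * k3[k];
    deriv(i, t + h, tmp.data(), k4.data());
    for (int k = 0; k < d; ++k)
      s[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (!row_finite(s.data(), d)) {
      ok = false;
      i_fail = i + 1;
      break;
    }
    for (int k = 0; k < d; ++k) out(i + 1, k) = s[k];
  }
  return List::create(_["trajectory"] = out, _["ok"] = ok,
                      _["i_fail"] = i_fail);
}

// [[Rcpp::export]]
List integrate_het_cpp(NumericMatrix pac, IntegerVector off, NumericMatrix mus,
                       NumericVector y0, double h, int n) {
  // pac: 3 x (a, u, f, d, e, K); off: delay sample offsets (SA entry unused)
  // mus: 4 x (k, c, w1, w2, b, g, h, C)
  // state: x1,y1,x2,y2,x3,y3,z1,v1,...,z4,v4
  const int d = 14;
  NumericMatrix out(n + 1, d);
  std::vector<double> s(d), k1(d), k2(d), k3(d), k4(d), tmp(d);
  for (int k = 0; k < d; ++k) {
    s[k] = y0[k];
    out(0, k) = s[k];
  }
  double ydel[3] = {0.0, 0.0, 0.0};
  bool ok = true;
  int i_fail = -1;

  auto deriv = [&](const double* st, double* ds) {
    for (int p = 0; p < 3; ++p) {
      double x = st[2 * p], y = st[2 * p + 1];
      double coup = (p > 0) ? pac(p, 5) * (ydel[p] - y) : 0.0;
      ds[2 * p] = y;
      ds[2 * p + 1] = -pac(p, 0) * (x * x - pac(p, 1)) * y -
                      pac(p, 2) * x * (x + pac(p, 3)) * (x + pac(p, 4)) + coup;
    }
    double Y[4] = {st[1], -st[1], st[5], -st[5]};
    for (int j = 0; j < 4; ++j) {
      double z = st[6 + 2 * j], v = st[7 + 2 * j];
      double I = (Y[j] > 0.0) ? mus(j, 7) * Y[j] : 0.0;
      ds[6 + 2 * j] =
          mus(j, 0) * (-mus(j, 1) * z * (z - mus(j, 2)) * (z - mus(j, 3)) -
                       mus(j, 4) * v - mus(j, 5) * v * z + I);
      ds[7 + 2 * j] = mus(j, 0) * mus(j, 6) * (z - v);
    }
  };

  for (int i = 0; i < n; ++i) {
    // frozen start-of-step delayed lookups: AV sees y1, HP sees y2
    int jAV = i - off[1];
    int jHP = i - off[2];
    ydel[1] = (jAV < 0) ? y0[1] : out(jAV, 1);
    ydel[2] = (jHP < 0) ? y0[3] : out(jHP, 3);

    deriv(s.data(), k1.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k1[k];
    deriv(tmp.data(), k2.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k2[k];
    deriv(tmp.data(), k3.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + h * k3[k];
    deriv(tmp.data(), k4.data());
    for (int k = 0; k < d; ++k)
      s[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (!row_finite(s.data(), d)) {
      ok = false;
      i_fail = i + 1;
      break;
    }
    for (int k = 0; k < d; ++k) out(i + 1, k) = s[k];
  }
  return List::create(_["trajectory"] = out, _["ok"] = ok,
                      _["i_fail"] = i_fail);
}

// [[Rcpp::export]]
List integrate_rd_cpp(double H, double C, double beta, NumericVector y0,
                      double h, int n) {
  return rk4_drive(
      [&](int i, double t, const double* s, double* ds) {
        (void)i;
        (void)t;
        double x1 = s[0], x2 = s[1], x3 = s[2], x4 = s[3];
        ds[0] = x1 - x2 - C * x1 * x2 - x1 * x2 * x2;
        ds[1] = H * x1 - 3.0 * x2 + C * x1 * x2 + x1 * x2 * x2 +
                beta * (x4 - x2);
        ds[2] = x3 - x4 - C * x3 * x4 - x3 * x4 * x4;
        ds[3] = H * x3 - 3.0 * x4 + C * x3 * x4 + x3 * x4 * x4 +
                2.0 * beta * (x2 - x4);
      },
      y0, h, n, 4);
}

// [[Rcpp::export]]
List integrate_ring_cpp(NumericMatrix nodes, NumericVector kc,
                        IntegerVector off, NumericVector y0, double h, int n) {
  // nodes: 3 x (a, w1, w2, d, e, rho, omega)
  // couplings in order SA_AV, SA_HP, AV_SA, AV_HP, HP_SA, HP_AV
  // partner position column per coupling:
  static const int pcol[6] = {2, 4, 0, 4, 0, 2};
  // couplings entering each node's velocity equation:
  static const int ncoup[3][2] = {{0, 1}, {2, 3}, {4, 5}};
  const int d = 6;
  NumericMatrix out(n + 1, d);
  std::vector<double> s(d), k1(d), k2(d), k3(d), k4(d), tmp(d);
  for (int k = 0; k < d; ++k) {
    s[k] = y0[k];
    out(0, k) = s[k];
  }
  double del[6];
  bool ok = true;
  int i_fail = -1;

  // The restoring cubic is normalized by d*e so each node's small-amplitude
  // frequency is ~1 rad per model time unit (source oscillator family
  // convention). Tabulated drive frequencies are expressed in the
  // un-normalized time base, whose natural frequency is sqrt(|d*e|); they are
  // converted by the same factor so the drive-to-natural frequency ratio of
  // the parameter set is preserved.
  double omw[3];
  for (int p = 0; p < 3; ++p)
    omw[p] = nodes(p, 6) / std::sqrt(std::abs(nodes(p, 3) * nodes(p, 4)));

  auto deriv = [&](double t, const double* st, double* ds) {
    for (int p = 0; p < 3; ++p) {
      double x = st[2 * p], v = st[2 * p + 1];
      double coup = 0.0;
      for (int c = 0; c < 2; ++c) {
        int ci = ncoup[p][c];
        coup += kc[ci] * (x - del[ci]);
      }
      ds[2 * p] = v;
      ds[2 * p + 1] = -nodes(p, 0) * v * (x - nodes(p, 1)) * (x - nodes(p, 2)) +
                      nodes(p, 5) * std::sin(omw[p] * t) -
                      x * (x - nodes(p, 3)) * (x - nodes(p, 4)) /
                          (nodes(p, 3) * nodes(p, 4)) -
                      coup;
    }
  };

  for (int i = 0; i < n; ++i) {
    double t = i * h;
    for (int c = 0; c < 6; ++c) {
      int j = i - off[c];
      del[c] = (j < 0) ? y0[pcol[c]] : out(j, pcol[c]);
    }
    deriv(t, s.data(), k1.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k1[k];
    deriv(t + 0.5 * h, tmp.data(), k2.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + 0.5 * h * k2[k];
    deriv(t + 0.5 * h, tmp.data(), k3.data());
    for (int k = 0; k < d; ++k) tmp[k] = s[k] + h * k3[k];
    deriv(t + h, tmp.data(), k4.data());
    for (int k = 0; k < d; ++k)
      s[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (!row_finite(s.data(), d)) {
      ok = false;
      i_fail = i + 1;
      break;
    }
    for (int k = 0; k < d; ++k) out(i + 1, k) = s[k];
  }
  return List::create(_["trajectory"] = out, _["ok"] = ok,
                      _["i_fail"] = i_fail);
}

static inline double wrap_pi(double x) {
  // x - 2*pi*floor((x + pi) / (2*pi)) maps to [-pi, pi)
  return x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
}

// [[Rcpp::export]]
List integrate_qp_cpp(NumericVector a, NumericVector b, NumericVector th,
                      double A, double fr, NumericVector omega,
                      NumericVector y0, double h, int n) {
  // state: x, y, P, C, T; kernels ordered P-, P+, Q, R, S, T-, T+
  const bool om_scalar = (omega.size() == 1);
  double om = omega[0];
  return rk4_drive(
      [&](int i, double t, const double* s, double* ds) {
        double w = om_scalar ? om : omega[i];
        double x = s[0], y = s[1];
        double r = std::sqrt(x * x + y * y);
        double al = 1.0 - r;
        double theta = std::atan2(y, x);
        double z0 = A * std::sin(2.0 * M_PI * fr * t);
        double push[3] = {0.0, 0.0, 0.0};
        for (int k = 0; k < 7; ++k) {
          double dth = wrap_pi(theta - th[k]);
          double val = a[k] * dth * std::exp(-dth * dth / (2.0 * b[k] * b[k]));
          int g = (k < 2) ? 0 : (k < 5 ? 1 : 2);
          push[g] += val;
        }
        ds[0] = al * x - w * y;
        ds[1] = al * y + w * x;
        ds[2] = -push[0] - (s[2] - z0);
        ds[3] = -push[1] - (s[3] - z0);
        ds[4] = -push[2] - (s[4] - z0);
      },
      y0, h, n, 5);
}
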