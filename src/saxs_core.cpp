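#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// sinc(x) = sin(x)/x with the analytic q -> 0 limit
static inline double sinc(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// second derivative of sinc
static inline double sinc_dd(double x) {
  if (std::fabs(x) < 1e-3) return -1.0 / 3.0 + x * x / 10.0;
  double x2 = x * x;
  return -std::sin(x) / x - 2.0 * std::cos(x) / x2 +
         2.0 * std::sin(x) / (x2 * x);
}

// Exact Debye sum: I(q) = sum_ij f_i(q) f_j(q) sinc(q r_ij)
// with f_i(q) = b_i exp(-q^2 sigma_i^2 / 2).
// [[Rcpp::export(name = ".debye_exact_cpp")]]
NumericVector debye_exact_cpp(NumericMatrix pos, NumericVector b,
                              NumericVector sig, NumericVector q) {
  const int n = pos.nrow(), nq = q.size();
  NumericVector I(nq);
  // precompute form factors F[k, i]
  std::vector<double> F((size_t)nq * n);
  for (int k = 0; k < nq; ++k) {
    double q2h = 0.5 * q[k] * q[k];
    for (int i = 0; i < n; ++i)
      F[(size_t)k * n + i] = b[i] * std::exp(-q2h * sig[i] * sig[i]);
  }
  // self terms
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = F[(size_t)k * n + i];
      s += f * f;
    }
    I[k] = s;
  }
  const double *x = &pos(0, 0), *y = &pos(0, 1), *z = &pos(0, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        I[k] += 2.0 * F[(size_t)k * n + i] * F[(size_t)k * n + j] *
                sinc(q[k] * r);
      }
    }
  }
  return I;
}

// Cross term between two bead sets: 2 * sum_i sum_j f_i g_j sinc(q r_ij)
// [[Rcpp::export(name = ".debye_cross_cpp")]]
NumericVector debye_cross_cpp(NumericMatrix posA, NumericVector bA,
                              NumericVector sigA, NumericMatrix posB,
                              NumericVector bB, NumericVector sigB,
                              NumericVector q) {
  const int nA = posA.nrow(), nB = posB.nrow(), nq = q.size();
  NumericVector I(nq);
  std::vector<double> FA((size_t)nq * nA), FB((size_t)nq * nB);
  for (int k = 0; k < nq; ++k) {
    double q2h = 0.5 * q[k] * q[k];
    for (int i = 0; i < nA; ++i)
      FA[(size_t)k * nA + i] = bA[i] * std::exp(-q2h * sigA[i] * sigA[i]);
    for (int j = 0; j < nB; ++j)
      FB[(size_t)k * nB + j] = bB[j] * std::exp(-q2h * sigB[j] * sigB[j]);
  }
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      double dx = posA(i, 0) - posB(j, 0);
      double dy = posA(i, 1) - posB(j, 1);
      double dz = posA(i, 2) - posB(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k)
        I[k] += 2.0 * FA[(size_t)k * nA + i] * FB[(size_t)k * nB + j] *
                sinc(q[k] * r);
    }
  }
  return I;
}

// Histogram-accelerated Debye: pair distances binned (bin centres, half-open
// bins) separately per pair of bead types; a type shares (b, sigma).
// typ is a 0-based type index per bead.
// [[Rcpp::export(name = ".debye_hist_cpp")]]
NumericVector debye_hist_cpp(NumericMatrix pos, IntegerVector typ,
                             NumericVector btype, NumericVector sigtype,
                             NumericVector q, double dr) {
  const int n = pos.nrow(), nq = q.size(), nt = btype.size();
  // max distance
  double rmax = 0.0;
  const double *x = &pos(0, 0), *y = &pos(0, 1), *z = &pos(0, 2);
  // bounding-box diagonal bounds rmax cheaply
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i) {
    if (x[i] < lo[0]) lo[0] = x[i];
    if (x[i] > hi[0]) hi[0] = x[i];
    if (y[i] < lo[1]) lo[1] = y[i];
    if (y[i] > hi[1]) hi[1] = y[i];
    if (z[i] < lo[2]) lo[2] = z[i];
    if (z[i] > hi[2]) hi[2] = z[i];
  }
  rmax = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                   (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                   (hi[2] - lo[2]) * (hi[2] - lo[2]));
  int nbin = (int)std::floor(rmax / dr) + 2;
  int npair_t = nt * (nt + 1) / 2;  // unordered type pairs
  std::vector<double> H((size_t)npair_t * nbin, 0.0);
  std::vector<double> HR((size_t)npair_t * nbin, 0.0);   // sum of r
  std::vector<double> HR2((size_t)npair_t * nbin, 0.0);  // sum of r^2
  auto pairidx = [nt](int a, int b) {
    if (a > b) std::swap(a, b);
    return a * nt - a * (a - 1) / 2 + (b - a);
  };
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int ib = (int)std::floor(r / dr);
      size_t k = (size_t)pairidx(typ[i], typ[j]) * nbin + ib;
      H[k] += 2.0;
      HR[k] += 2.0 * r;
      HR2[k] += 2.0 * r * r;
    }
  }
  // per-type self counts
  std::vector<double> nself(nt, 0.0);
  for (int i = 0; i < n; ++i) nself[typ[i]] += 1.0;

  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double q2h = 0.5 * q[k] * q[k];
    std::vector<double> ft(nt);
    for (int t = 0; t < nt; ++t)
      ft[t] = btype[t] * std::exp(-q2h * sigtype[t] * sigtype[t]);
    double s = 0.0;
    for (int t = 0; t < nt; ++t) s += nself[t] * ft[t] * ft[t];
    for (int a = 0; a < nt; ++a) {
      for (int b2 = a; b2 < nt; ++b2) {
        const double fab = ft[a] * ft[b2];
        size_t off = (size_t)pairidx(a, b2) * nbin;
        const double *h = &H[off];
        const double *hr = &HR[off];
        const double *hr2 = &HR2[off];
        for (int ib = 0; ib < nbin; ++ib) {
          if (h[ib] == 0.0) continue;
          // evaluate at the bin's mean distance with a second-order
          // within-bin variance correction
          double rc = hr[ib] / h[ib];
          double var = hr2[ib] / h[ib] - rc * rc;
          if (var < 0.0) var = 0.0;
          double xq = q[k] * rc;
          s += fab * h[ib] *
               (sinc(xq) + 0.5 * var * q[k] * q[k] * sinc_dd(xq));
        }
      }
    }
    I[k] = s;
  }
  return I;
}

// Excluded-volume clash penalty between two bead sets:
// sum over pairs with r < r_clash of (r_clash - r)^2
// [[Rcpp::export(name = ".clash_penalty_cpp")]]
double clash_penalty_cpp(NumericMatrix posA, NumericMatrix posB,
                         double r_clash) {
  const int nA = posA.nrow(), nB = posB.nrow();
  const double rc2 = r_clash * r_clash;
  double e = 0.0;
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      double dx = posA(i, 0) - posB(j, 0);
      double dy = posA(i, 1) - posB(j, 1);
      double dz = posA(i, 2) - posB(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2) {
        double d = r_clash - std::sqrt(r2);
        e += d * d;
      }
    }
  }
  return e;
}

// Shrake-Rupley solvent-accessible surface area.
// pos: n x 3 coordinates, rad: per-atom radius (already + probe),
// n_points: sphere quadrature points (golden-spiral lattice).
// Returns per-atom accessible area in A^2.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix pos, NumericVector rad, int n_points) {
  const int n = pos.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    double zt = 1.0 - 2.0 * (p + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zt * zt));
    double th = ga * p;
    sx[p] = r * std::cos(th);
    sy[p] = r * std::sin(th);
    sz[p] = zt;
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    // neighbour list
    nb.clear();
    double cut = rad[i] + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double c = rad[i] + rad[j];
      if (r2 < cut * cut && r2 < c * c) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = pos(i, 0) + rad[i] * sx[p];
      double py = pos(i, 1) + rad[i] * sy[p];
      double pz = pos(i, 2) + rad[i] * sz[p];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - pos(j, 0), dy = py - pos(j, 1), dz = pz - pos(j, 2);
        if (dx * dx + dy * dy + dz * dz < rad[j] * rad[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * rad[i] * rad[i] * acc / n_points;
  }
  return area;
}
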