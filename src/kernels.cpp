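#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Apex height of a hard spherical tip resting on a set of spherical beads.
// Pixel (i, j) (0-based, i = column/x, j = row/y) sits at
// (x0 + i*px, y0 + j*px).  Heights below the support plane are clamped to 0.
// [[Rcpp::export]]
NumericMatrix render_heights_cpp(NumericVector x, NumericVector y, NumericVector z,
                                 NumericVector rad, double tip_r, double px,
                                 int nx, int ny, double x0, double y0) {
  NumericMatrix h(ny, nx);
  const int nb = x.size();
  for (int b = 0; b < nb; ++b) {
    const double reach = tip_r + rad[b];
    const double r2 = reach * reach;
    int i0 = (int)std::floor((x[b] - reach - x0) / px);
    int i1 = (int)std::ceil((x[b] + reach - x0) / px);
    int j0 = (int)std::floor((y[b] - reach - y0) / px);
    int j1 = (int)std::ceil((y[b] + reach - y0) / px);
    i0 = std::max(i0, 0);
    j0 = std::max(j0, 0);
    i1 = std::min(i1, nx - 1);
    j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      const double dy = y0 + j * px - y[b];
      for (int i = i0; i <= i1; ++i) {
        const double dx = x0 + i * px - x[b];
        const double d2 = dx * dx + dy * dy;
        if (d2 <= r2) {
          const double ht = z[b] + std::sqrt(r2 - d2) - tip_r;
          if (ht > h(j, i)) h(j, i) = ht;
        }
      }
    }
  }
  for (R_xlen_t k = 0; k < h.size(); ++k) {
    if (h[k] < 0.0) h[k] = 0.0;
  }
  return h;
}

// Uncentered normalized cross-correlation over the union footprint of pixels
// where either image exceeds floor_h.  Returns NA when a footprint side is
// identically zero.
// [[Rcpp::export]]
double cc_footprint_cpp(NumericMatrix a, NumericMatrix b, double floor_h) {
  double num = 0.0, da = 0.0, db = 0.0;
  const R_xlen_t n = a.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double av = a[k], bv = b[k];
    if (av > floor_h || bv > floor_h) {
      num += av * bv;
      da += av * av;
      db += bv * bv;
    }
  }
  if (da <= 0.0 || db <= 0.0) return NA_REAL;
  return num / (std::sqrt(da) * std::sqrt(db));
}

// Soft-core repulsion plus screened-charge (Debye-Hueckel) term between
// non-bonded beads.  `code` is an integer per bead; pairs whose codes differ
// by <= 1 (same or sequence-adjacent nucleotide) are skipped, as are pairs
// listed in `excl_keys` (sorted keys i*n + j with i < j, 0-based).
// [[Rcpp::export]]
double contact_energy_cpp(NumericMatrix xyz, IntegerVector code, LogicalVector is_bb,
                          NumericVector excl_keys, double dc, double k_sc,
                          double dh_amp, double dh_lambda, double dh_cut) {
  const int n = xyz.nrow();
  const double cut = std::max(dc, dh_cut);
  const double cut2 = cut * cut;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int dcode = code[j] - code[i];
      if (dcode < 0) dcode = -dcode;
      if (dcode <= 1) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      const double key = (double)i * n + j;
      if (std::binary_search(excl_keys.begin(), excl_keys.end(), key)) continue;
      const double d = std::sqrt(d2);
      if (d < dc) {
        const double t = (dc - d) / dc;
        e += k_sc * t * t;
      }
      if (is_bb[i] && is_bb[j] && d < dh_cut) {
        e += dh_amp * std::exp(-d / dh_lambda) / std::max(d, 1.0);
      }
    }
  }
  return e;
}

// Smallest distance between beads that are neither sequence-adjacent
// (|code difference| <= 1) nor excluded.  Used for clash auditing.
// [[Rcpp::export]]
double min_nonbonded_dist_cpp(NumericMatrix xyz, IntegerVector code,
                              NumericVector excl_keys) {
  const int n = xyz.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int dcode = code[j] - code[i];
      if (dcode < 0) dcode = -dcode;
      if (dcode <= 1) continue;
      const double key = (double)i * n + j;
      if (std::binary_search(excl_keys.begin(), excl_keys.end(), key)) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  }
  return best;
}

// Debye scattering sum for point beads with q-independent form factors:
// I(q) = sum_u sum_v f_u f_v sinc(q d_uv).
// [[Rcpp::export]]
NumericVector debye_cpp(NumericMatrix xyz, NumericVector q, NumericVector f) {
  const int n = xyz.nrow();
  const int nq = q.size();
  NumericVector I(nq);
  double s2 = 0.0;
  for (int i = 0; i < n; ++i) s2 += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = s2;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ff = 2.0 * f[i] * f[j];
      for (int k = 0; k < nq; ++k) {
        const double qd = q[k] * d;
        I[k] += ff * (qd < 1e-8 ? 1.0 : std::sin(qd) / qd);
      }
    }
  }
  return I;
}
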