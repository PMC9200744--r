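#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Debye double sum for one structure on a Q grid.
// I(Q) = sum_i sum_j f_i f_j sinc(Q r_ij), sinc(0) = 1.
// [[Rcpp::export]]
NumericVector cpp_debye_curve(NumericMatrix coords, NumericVector weights,
                              NumericVector q) {
  const int n = coords.nrow(), nq = q.size();
  NumericVector out(nq);
  double fsum = 0.0, f2sum = 0.0;
  for (int i = 0; i < n; ++i) { fsum += weights[i]; f2sum += weights[i] * weights[i]; }
  // self terms: sum f_i^2 at every Q
  for (int k = 0; k < nq; ++k) out[k] = f2sum;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double fi = weights[i];
    if (fi == 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      const double fj = weights[j];
      if (fj == 0.0) continue;
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
                   dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ff2 = 2.0 * fi * fj;
      for (int k = 0; k < nq; ++k) {
        const double qr = q[k] * r;
        out[k] += (qr == 0.0) ? ff2 : ff2 * std::sin(qr) / qr;
      }
    }
  }
  return out;
}

// Per-frame Debye curves for a trajectory stored as an n_beads x 3 x n_frames
// array, returned as an n_frames x n_q matrix (unnormalized).
// [[Rcpp::export]]
NumericMatrix cpp_debye_series(NumericVector coords_array, int n_beads,
                               int n_frames, NumericVector weights,
                               NumericVector q) {
  const int nq = q.size();
  NumericMatrix out(n_frames, nq);
  const double *base = REAL(coords_array);
  NumericMatrix frame(n_beads, 3);
  for (int f = 0; f < n_frames; ++f) {
    const double *p = base + (R_xlen_t)f * n_beads * 3;
    for (int b = 0; b < n_beads; ++b) {
      frame(b, 0) = p[b];
      frame(b, 1) = p[b + n_beads];
      frame(b, 2) = p[b + 2 * n_beads];
    }
    NumericVector curve = cpp_debye_curve(frame, weights, q);
    for (int k = 0; k < nq; ++k) out(f, k) = curve[k];
  }
  return out;
}

// Weighted two-parameter fit of I_sim = c * m - offs against y with weights w,
// minimizing sum w * (y - c*m + offs)^2. Fills c, offs, chisq (divisor N-1)
// and the maximum squared residual over the index set band (0-based).
static inline void fit_window(const double *m, const double *y, const double *w,
                              int nq, const int *band, int nband,
                              double &c, double &offs, double &chi2,
                              double &band_max) {
  double Sw = 0, Sm = 0, Sy = 0, Smm = 0, Smy = 0;
  for (int k = 0; k < nq; ++k) {
    Sw += w[k]; Sm += w[k] * m[k]; Sy += w[k] * y[k];
    Smm += w[k] * m[k] * m[k]; Smy += w[k] * m[k] * y[k];
  }
  const double denom = Smm - Sm * Sm / Sw;
  c = (Smy - Sy * Sm / Sw) / denom;
  offs = (c * Sm - Sy) / Sw;
  double ss = 0;
  band_max = 0;
  for (int k = 0; k < nq; ++k) {
    const double r = y[k] - c * m[k] + offs;
    ss += w[k] * r * r;
  }
  for (int b = 0; b < nband; ++b) {
    const int k = band[b];
    const double r = y[k] - c * m[k] + offs;
    const double sr = w[k] * r * r;
    if (sr > band_max) band_max = sr;
  }
  chi2 = ss / (nq - 1);
}

// Scan all contiguous windows [s, s+len) from the longest length down and
// return the first (longest, earliest-start) window passing the criteria.
// prefix: (n_frames+1) x n_q cumulative row sums of per-frame profiles.
// band_idx: 0-based column indices with q < resid_q_max.
// Returns c(start, end, c, offs, chi2, band_max, found).
// [[Rcpp::export]]
NumericVector cpp_longest_window(NumericMatrix prefix, NumericVector y,
                                 NumericVector w, IntegerVector band_idx,
                                 double chi2_max, double resid_max,
                                 bool use_band) {
  const int n = prefix.nrow() - 1, nq = prefix.ncol();
  std::vector<double> m(nq);
  std::vector<int> band(band_idx.begin(), band_idx.end());
  const int nband = band.size();
  for (int len = n; len >= 1; --len) {
    for (int s = 0; s + len <= n; ++s) {
      const int e = s + len;
      for (int k = 0; k < nq; ++k) m[k] = prefix(e, k) - prefix(s, k);
      double c, offs, chi2, band_max;
      fit_window(m.data(), REAL(y), REAL(w), nq, band.data(), nband,
                 c, offs, chi2, band_max);
      bool pass = chi2 < chi2_max;
      if (pass && use_band) pass = band_max < resid_max;
      if (pass)
        return NumericVector::create(s, e, c, offs, chi2, band_max, 1.0);
    }
  }
  return NumericVector::create(NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL,
                               NA_REAL, 0.0);
}

// Enumerate every window of length >= min_len that passes the criteria,
// in lexicographic (start, end) order. Returns a matrix with columns
// start, end, c, offs, chi2, band_max.
// [[Rcpp::export]]
NumericMatrix cpp_enumerate_windows(NumericMatrix prefix, NumericVector y,
                                    NumericVector w, IntegerVector band_idx,
                                    double chi2_max, double resid_max,
                                    bool use_band, int min_len) {
  const int n = prefix.nrow() - 1, nq = prefix.ncol();
  std::vector<double> m(nq);
  std::vector<int> band(band_idx.begin(), band_idx.end());
  const int nband = band.size();
  std::vector<double> rows;
  for (int s = 0; s < n; ++s) {
    for (int e = s + min_len; e <= n; ++e) {
      for (int k = 0; k < nq; ++k) m[k] = prefix(e, k) - prefix(s, k);
      double c, offs, chi2, band_max;
      fit_window(m.data(), REAL(y), REAL(w), nq, band.data(), nband,
                 c, offs, chi2, band_max);
      bool pass = chi2 < chi2_max;
      if (pass && use_band) pass = band_max < resid_max;
      if (pass) {
        rows.push_back(s); rows.push_back(e); rows.push_back(c);
        rows.push_back(offs); rows.push_back(chi2); rows.push_back(band_max);
      }
    }
  }
  const int nr = rows.size() / 6;
  NumericMatrix out(nr, 6);
  for (int i = 0; i < nr; ++i)
    for (int jcol = 0; jcol < 6; ++jcol) out(i, jcol) = rows[6 * i + jcol];
  colnames(out) = CharacterVector::create("start", "end", "c", "offs",
                                          "chi2", "band_max");
  return out;
}
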