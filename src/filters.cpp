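#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filtering of a channels x samples matrix through cascaded
// biquad sections (direct form II transposed, zero initial state).
// `sos` is an n_sections x 6 matrix of (b0, b1, b2, a0, a1, a2) with
// a0 == 1. Returns a new matrix; the input is not modified.
//
// R stores the matrix column-major, i.e. one sample of all channels is
// contiguous, so the sample loop is outermost and the channel loop
// innermost with per-(channel, section) filter state kept resident.
// [[Rcpp::export]]
NumericMatrix sosfilt_matrix(const NumericMatrix& sos,
                             const NumericMatrix& x) {
  const int ns = sos.nrow();
  const int nch = x.nrow();
  const R_xlen_t nsmp = x.ncol();
  NumericMatrix y(nch, nsmp);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
  }
  // state, indexed [section * nch + channel]
  std::vector<double> z1((size_t)ns * nch, 0.0), z2((size_t)ns * nch, 0.0);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t t = 0; t < nsmp; ++t) {
    const double* xc = xp + (size_t)t * nch;
    double* yc = yp + (size_t)t * nch;
    for (int s = 0; s < ns; ++s) {
      const double cb0 = b0[s], cb1 = b1[s], cb2 = b2[s];
      const double ca1 = a1[s], ca2 = a2[s];
      double* z1s = &z1[(size_t)s * nch];
      double* z2s = &z2[(size_t)s * nch];
      const double* in = (s == 0) ? xc : yc;
      for (int ch = 0; ch < nch; ++ch) {
        const double v = in[ch];
        const double out = cb0 * v + z1s[ch];
        z1s[ch] = cb1 * v - ca1 * out + z2s[ch];
        z2s[ch] = cb2 * v - ca2 * out;
        yc[ch] = out;
      }
    }
  }
  return y;
}

// Subtract the per-sample median across channels; returns a new matrix.
// [[Rcpp::export]]
NumericMatrix subtract_column_medians(const NumericMatrix& x) {
  const int nch = x.nrow();
  const R_xlen_t nsmp = x.ncol();
  NumericMatrix y(nch, nsmp);
  std::vector<double> col(nch);
  const int mid = nch / 2;
  const bool odd = (nch % 2) == 1;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t t = 0; t < nsmp; ++t) {
    const double* xc = xp + (size_t)t * nch;
    double* yc = yp + (size_t)t * nch;
    std::copy(xc, xc + nch, col.begin());
    std::nth_element(col.begin(), col.begin() + mid, col.end());
    double m = col[mid];
    if (!odd) {
      double lo = *std::max_element(col.begin(), col.begin() + mid);
      m = lo + (m - lo) / 2.0;  // mean of the two middle order stats
    }
    for (int ch = 0; ch < nch; ++ch) yc[ch] = xc[ch] - m;
  }
  return y;
}
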