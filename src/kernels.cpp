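// Hot inner kernels of the fOCT analysis: windowed inter-frame
// decorrelation over a whole B-M series, and the run-length
// significance detector. Both are O(n) passes that would otherwise
// allocate many full-stack temporaries in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// windowed sums of src (nz x nx) via an integral image; window
// wz x wx centered, truncated at the edges
static void box_sum_2d(const double* src, double* dst, int nz, int nx,
                       int wz, int wx, std::vector<double>& ii) {
  // integral image with zero top row / left column, (nz+1) x (nx+1)
  const int Z = nz + 1;
  for (int j = 0; j <= nx; ++j) ii[(size_t)j * Z] = 0.0;
  for (int i = 0; i <= nz; ++i) ii[i] = 0.0;
  for (int j = 1; j <= nx; ++j) {
    double run = 0.0;
    const double* col = src + (size_t)(j - 1) * nz;
    double* icol = &ii[(size_t)j * Z];
    const double* iprev = &ii[(size_t)(j - 1) * Z];
    for (int i = 1; i <= nz; ++i) {
      run += col[i - 1];
      icol[i] = iprev[i] + run;
    }
  }
  const int hz1 = (wz - 1) / 2, hz2 = wz - 1 - hz1;
  const int hx1 = (wx - 1) / 2, hx2 = wx - 1 - hx1;
  for (int j = 0; j < nx; ++j) {
    int jlo = j - hx1; if (jlo < 0) jlo = 0;
    int jhi = j + hx2 + 1; if (jhi > nx) jhi = nx;
    const double* ilo = &ii[(size_t)jlo * Z];
    const double* ihi = &ii[(size_t)jhi * Z];
    double* dcol = dst + (size_t)j * nz;
    for (int i = 0; i < nz; ++i) {
      int klo = i - hz1; if (klo < 0) klo = 0;
      int khi = i + hz2 + 1; if (khi > nz) khi = nz;
      dcol[i] = ihi[khi] - ihi[klo] - ilo[khi] + ilo[klo];
    }
  }
}

// [[Rcpp::export(name = ".decorr_series_cpp")]]
NumericVector decorr_series_cpp(NumericVector arr, int nz, int nx, int nt,
                                int wz, int wx) {
  if ((size_t)nz * nx * nt != (size_t)arr.size())
    stop("array size mismatch");
  if (nt < 2) stop("need at least 2 frames");
  const size_t npx = (size_t)nz * nx;
  NumericVector out((R_xlen_t)(npx * (nt - 1)));
  std::vector<double> ab(npx), aa(npx), bb(npx);
  std::vector<double> sab(npx), saa(npx), sbb(npx);
  std::vector<double> ii((size_t)(nz + 1) * (nx + 1));
  const double* a = REAL(arr);
  double* o = REAL(out);
  for (int k = 0; k + 1 < nt; ++k) {
    const double* A = a + npx * k;
    const double* B = A + npx;
    for (size_t p = 0; p < npx; ++p) {
      ab[p] = A[p] * B[p];
      aa[p] = A[p] * A[p];
      bb[p] = B[p] * B[p];
    }
    box_sum_2d(ab.data(), sab.data(), nz, nx, wz, wx, ii);
    box_sum_2d(aa.data(), saa.data(), nz, nx, wz, wx, ii);
    box_sum_2d(bb.data(), sbb.data(), nz, nx, wz, wx, ii);
    double* ok = o + npx * k;
    for (size_t p = 0; p < npx; ++p) {
      double den = std::sqrt(saa[p] * sbb[p]);
      double d = (den > 0.0) ? 1.0 - sab[p] / den : 0.0;
      if (!(d > 0.0)) d = 0.0;      // also catches NaN
      else if (d > 1.0) d = 1.0;
      ok[p] = d;
    }
  }
  return out;
}

// run-length detector: pos/neg run-start labels. A positive run
// starts at frame t iff the trace strictly exceeds thr_up at t ..
// t+L-1; negative analogously below thr_dn.
// [[Rcpp::export(name = ".sig_runs_cpp")]]
List sig_runs_cpp(NumericVector arr, NumericVector thr_up,
                  NumericVector thr_dn, int nz, int nx, int nt, int L) {
  const size_t npx = (size_t)nz * nx;
  if ((size_t)arr.size() != npx * nt) stop("array size mismatch");
  if ((size_t)thr_up.size() != npx || (size_t)thr_dn.size() != npx)
    stop("threshold size mismatch");
  if (L < 1 || L > nt) stop("invalid run length");
  LogicalVector pos((R_xlen_t)(npx * nt)), neg((R_xlen_t)(npx * nt));
  const double* a = REAL(arr);
  int* P = LOGICAL(pos);
  int* N = LOGICAL(neg);
  for (size_t p = 0; p < npx; ++p) {
    const double tu = thr_up[p], td = thr_dn[p];
    int cu = 0, cd = 0;
    for (int t = 0; t < nt; ++t) {
      const double v = a[p + npx * t];
      cu = (v > tu) ? cu + 1 : 0;
      cd = (v < td) ? cd + 1 : 0;
      if (cu >= L) P[p + npx * (t - L + 1)] = 1;
      if (cd >= L) N[p + npx * (t - L + 1)] = 1;
    }
  }
  return List::create(Named("pos") = pos, Named("neg") = neg);
}

// dilate run-start labels to run coverage: frame t is covered if a
// run started at any of t-L+1 .. t
// [[Rcpp::export(name = ".coverage_cpp")]]
IntegerVector coverage_cpp(LogicalVector pos, LogicalVector neg,
                           int nz, int nx, int nt, int L) {
  const size_t npx = (size_t)nz * nx;
  if ((size_t)pos.size() != npx * nt || (size_t)neg.size() != npx * nt)
    stop("array size mismatch");
  IntegerVector out((R_xlen_t)(npx * nt));
  const int* P = LOGICAL(pos);
  const int* N = LOGICAL(neg);
  int* O = INTEGER(out);
  for (size_t p = 0; p < npx; ++p) {
    int up = 0, dn = 0;   // frames of coverage remaining
    for (int t = 0; t < nt; ++t) {
      const size_t at = p + npx * t;
      if (P[at]) up = L;
      if (N[at]) dn = L;
      O[at] = (up > 0) ? 1 : ((dn > 0) ? -1 : 0);
      if (up > 0) --up;
      if (dn > 0) --dn;
    }
  }
  return out;
}
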