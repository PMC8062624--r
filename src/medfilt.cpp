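#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

//' Rectangular 2D median filter with zero padding
//'
//' Median filter over an arbitrary (possibly even-sized) rectangular window,
//' with the window centre at ceiling((k+1)/2) along each axis and zero
//' padding outside the image, matching the usual even-window convention of
//' order-statistic filters.  For an even number of window samples the median
//' is the mean of the two middle order statistics.
//'
//' @param x numeric matrix.
//' @param kr,kc window extent in rows and columns (>= 1).
//' @return filtered matrix of the same dimensions.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix medfilt2_rect(NumericMatrix x, int kr, int kc) {
  if (kr < 1 || kc < 1)
    stop("window sizes must be >= 1");
  int nr = x.nrow(), nc = x.ncol();
  if (kr > nr || kc > nc)
    stop("median window larger than image");
  // centre index (1-based) is ceiling((k+1)/2): offsets -(c-1) .. k-c
  int cr = (kr + 2) / 2, cc = (kc + 2) / 2;
  int r0 = 1 - cr, r1 = kr - cr, c0 = 1 - cc, c1 = kc - cc;
  int nwin = kr * kc;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(nwin);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = c0; dj <= c1; ++dj) {
        int jj = j + dj;
        for (int di = r0; di <= r1; ++di) {
          int ii = i + di;
          buf[m++] = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? x(ii, jj) : 0.0;
        }
      }
      int h = nwin / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + nwin);
      double med = buf[h];
      if (nwin % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}
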