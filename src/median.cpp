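#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact square-window median of a mirror-padded image. `padded` must carry a
// border of `half` pixels on every side; the result has the original
// (nr x nc) shape. The median of the odd (2*half+1)^2 sample count is the
// middle order statistic, found with nth_element.
// [[Rcpp::export]]
NumericMatrix median_filter_padded(NumericMatrix padded, int nr, int nc,
                                   int half) {
  const int side = 2 * half + 1;
  const int win = side * side;
  const int mid = win / 2;   // 0-based index of the middle element
  NumericMatrix out(nr, nc);
  std::vector<double> buf(win);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = 0; dc < side; ++dc)
        for (int dr = 0; dr < side; ++dr)
          buf[k++] = padded(r + dr, c + dc);
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(r, c) = buf[mid];
    }
  }
  return out;
}
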