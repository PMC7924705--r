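#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular Hough accumulator. An edge pixel (ey, ex) votes for an integer
// center (yc, xc) at radius r iff round(euclidean distance) == r. This
// membership rule is the package's pinned voting geometry; the test-suite
// brute-force voter implements the same rule independently.
//
// Coordinates are 0-based; the returned array has dim (h, w, nr) with
// acc[yc, xc, ir] = votes for center (yc, xc) at radii[ir].
// [[Rcpp::export]]
IntegerVector hough_accumulate_cpp(IntegerVector edge_y, IntegerVector edge_x,
                                   int h, int w, IntegerVector radii) {
  const int nr = radii.size();
  const int ne = edge_y.size();
  IntegerVector acc((R_xlen_t)h * w * nr);
  for (int ir = 0; ir < nr; ++ir) {
    const int r = radii[ir];
    std::vector<int> offy, offx;
    offy.reserve(8 * r + 8);
    offx.reserve(8 * r + 8);
    for (int dy = -r; dy <= r; ++dy) {
      for (int dx = -r; dx <= r; ++dx) {
        int rr = (int)std::lround(std::sqrt((double)(dy * dy + dx * dx)));
        if (rr == r) { offy.push_back(dy); offx.push_back(dx); }
      }
    }
    const R_xlen_t base = (R_xlen_t)ir * h * w;
    const size_t no = offy.size();
    for (int e = 0; e < ne; ++e) {
      const int ey = edge_y[e], ex = edge_x[e];
      for (size_t k = 0; k < no; ++k) {
        const int yc = ey + offy[k], xc = ex + offx[k];
        if (yc >= 0 && yc < h && xc >= 0 && xc < w)
          ++acc[base + (R_xlen_t)xc * h + yc];
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(h, w, nr);
  return acc;
}
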