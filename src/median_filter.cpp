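#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with window truncation at the volume boundary and the
// lower-median convention for even-sized (truncated) windows, so the
// output never contains a value absent from the input window.
// x is an array stored [y, x, z]; width is the odd window edge length;
// the window is width^3 for nz > 1 and width^2 for a single slice.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericVector median_filter_cpp(NumericVector x, int width) {
  IntegerVector dims = x.attr("dim");
  int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  if (width < 1 || width % 2 == 0) stop("width must be odd and >= 1");
  int h = width / 2;
  int hz = (nz > 1) ? h : 0;  // 2-D window for single-slice input
  NumericVector out(x.size());
  out.attr("dim") = dims;
  std::vector<double> win;
  win.reserve((size_t)width * width * width);
  for (int z = 0; z < nz; ++z) {
    int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
    for (int cx = 0; cx < nx; ++cx) {
      int x0 = std::max(0, cx - h), x1 = std::min(nx - 1, cx + h);
      for (int cy = 0; cy < ny; ++cy) {
        int y0 = std::max(0, cy - h), y1 = std::min(ny - 1, cy + h);
        win.clear();
        for (int zz = z0; zz <= z1; ++zz)
          for (int xx = x0; xx <= x1; ++xx)
            for (int yy = y0; yy <= y1; ++yy)
              win.push_back(x[(size_t)zz * nx * ny + (size_t)xx * ny + yy]);
        size_t k = (win.size() - 1) / 2;  // lower median when even
        std::nth_element(win.begin(), win.begin() + k, win.end());
        out[(size_t)z * nx * ny + (size_t)cx * ny + cy] = win[k];
      }
    }
  }
  return out;
}
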