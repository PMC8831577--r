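#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rank median over an axis-aligned box of (kr x kc x kz) voxels with
// replicate (nearest-value) padding at the borders. Kernel counts must be
// odd. Plain O(n * k^3) selection; volumes here are small.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int kr, int kc, int kz) {
  IntegerVector dims = vol.attr("dim");
  const int nr = dims[0], nc = dims[1], nz = dims[2];
  const int hr = kr / 2, hc = kc / 2, hz = kz / 2;

  NumericVector out(vol.size());
  out.attr("dim") = dims;
  std::vector<double> window;
  window.reserve((size_t)kr * kc * kz);

  for (int z = 0; z < nz; ++z) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        window.clear();
        for (int dz = -hz; dz <= hz; ++dz) {
          int zz = std::min(std::max(z + dz, 0), nz - 1);
          for (int dc = -hc; dc <= hc; ++dc) {
            int cc = std::min(std::max(c + dc, 0), nc - 1);
            for (int dr = -hr; dr <= hr; ++dr) {
              int rr = std::min(std::max(r + dr, 0), nr - 1);
              window.push_back(vol[rr + (size_t)nr * (cc + (size_t)nc * zz)]);
            }
          }
        }
        size_t mid = window.size() / 2;  // odd count: exact middle order stat
        std::nth_element(window.begin(), window.begin() + mid, window.end());
        out[r + (size_t)nr * (c + (size_t)nc * z)] = window[mid];
      }
    }
  }
  return out;
}
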