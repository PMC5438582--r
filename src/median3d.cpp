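#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3x3 median filter with reflected borders. The input is a numeric 3D
// array (dim = c(n1, n2, n3)); the neighbourhood is the full 27-voxel cube.
// Reflection: index -1 maps to 1, index n maps to n - 2 (R's 0-based view).
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol) {
  IntegerVector dm = vol.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  if (n1 < 3 || n2 < 3 || n3 < 3)
    stop("volume must be at least 3 voxels along every axis");
  NumericVector out(no_init(vol.size()));
  out.attr("dim") = dm;
  double nb[27];
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk;
          if (kk < 0) kk = 1; else if (kk >= n3) kk = n3 - 2;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj;
            if (jj < 0) jj = 1; else if (jj >= n2) jj = n2 - 2;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di;
              if (ii < 0) ii = 1; else if (ii >= n1) ii = n1 - 2;
              nb[m++] = v[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
            }
          }
        }
        std::nth_element(nb, nb + 13, nb + 27);
        o[i + (size_t)n1 * (j + (size_t)n2 * k)] = nb[13];
      }
    }
  }
  return out;
}
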