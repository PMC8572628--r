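#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact parallel-beam ray/pixel intersection lengths (Siddon alpha-list
// traversal).  Conventions shared with the R side:
//   * physical origin at the grid centre, x to the right, y up;
//   * pixel [row 0, col 0] is the top-left array element;
//   * pixel index (0-based) k = col * size + row, i.e. column-major order
//     of the R pixel matrix;
//   * ray index (0-based) c = angle * n_detectors + det;
//   * view angle a covers theta = pi * a / n_angles, detector bin d sits at
//     signed offset t = (d - (n_detectors - 1)/2) * det_spacing from the
//     rotation centre, the ray runs along (-sin theta, cos theta).
// Weights are intersection lengths in the units of pixel_spacing (mm).
// [[Rcpp::export]]
List siddon_weights(int n_angles, int n_detectors, double det_spacing,
                    int size, double pixel_spacing) {
  const double L = size * pixel_spacing;
  const double xmin = -L / 2.0;
  const double ymax = L / 2.0;
  const double eps = 1e-12 * std::max(1.0, L);

  std::vector<int> ray_idx;
  std::vector<int> pix_idx;
  std::vector<double> wts;
  std::vector<double> alphas;
  alphas.reserve(2 * size + 4);

  for (int a = 0; a < n_angles; ++a) {
    const double th = M_PI * a / n_angles;
    const double ct = std::cos(th), st = std::sin(th);
    const double dx = -st, dy = ct;
    for (int d = 0; d < n_detectors; ++d) {
      const double t = (d - 0.5 * (n_detectors - 1)) * det_spacing;
      const double px = t * ct, py = t * st;

      // clip the (doubly infinite) ray against the grid bounding box
      double s0 = -1e30, s1 = 1e30;
      bool miss = false;
      if (std::fabs(dx) > 1e-14) {
        double sa = (xmin - px) / dx, sb = (xmin + L - px) / dx;
        if (sa > sb) std::swap(sa, sb);
        s0 = std::max(s0, sa);
        s1 = std::min(s1, sb);
      } else if (px <= xmin || px >= xmin + L) {
        miss = true;
      }
      if (!miss && std::fabs(dy) > 1e-14) {
        double sa = (ymax - L - py) / dy, sb = (ymax - py) / dy;
        if (sa > sb) std::swap(sa, sb);
        s0 = std::max(s0, sa);
        s1 = std::min(s1, sb);
      } else if (!miss && (py <= ymax - L || py >= ymax)) {
        miss = true;
      }
      if (miss || s1 - s0 <= eps) continue;

      // all grid-line crossing parameters inside (s0, s1)
      alphas.clear();
      alphas.push_back(s0);
      alphas.push_back(s1);
      if (std::fabs(dx) > 1e-14) {
        for (int i = 0; i <= size; ++i) {
          const double s = (xmin + i * pixel_spacing - px) / dx;
          if (s > s0 + eps && s < s1 - eps) alphas.push_back(s);
        }
      }
      if (std::fabs(dy) > 1e-14) {
        for (int i = 0; i <= size; ++i) {
          const double s = (ymax - i * pixel_spacing - py) / dy;
          if (s > s0 + eps && s < s1 - eps) alphas.push_back(s);
        }
      }
      std::sort(alphas.begin(), alphas.end());

      const int c = a * n_detectors + d;
      for (size_t m = 0; m + 1 < alphas.size(); ++m) {
        const double len = alphas[m + 1] - alphas[m];
        if (len <= eps) continue;
        const double sm = 0.5 * (alphas[m] + alphas[m + 1]);
        const double mx = px + sm * dx;
        const double my = py + sm * dy;
        int col = (int)std::floor((mx - xmin) / pixel_spacing);
        int row = (int)std::floor((ymax - my) / pixel_spacing);
        if (col < 0 || col >= size || row < 0 || row >= size) continue;
        ray_idx.push_back(c);
        pix_idx.push_back(col * size + row);
        wts.push_back(len);
      }
    }
  }

  return List::create(
      _["ray"] = IntegerVector(ray_idx.begin(), ray_idx.end()),
      _["pixel"] = IntegerVector(pix_idx.begin(), pix_idx.end()),
      _["weight"] = NumericVector(wts.begin(), wts.end()));
}
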