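#include <Rcpp.h>
using namespace Rcpp;

// Parallel-beam ray-driven projector.
//
// Conventions (used package-wide): square H x W image, pixel spacing 1,
// centre at ((H-1)/2, (W-1)/2) in 0-based coordinates; x runs along columns,
// y along rows. Detector offsets r_j = j - (nd-1)/2. A ray for (theta, r)
// is p(t) = r*(cos t, sin t) + t*(-sin t, cos t), sampled with unit step in
// t and bilinear interpolation in the image. The adjoint scatters with the
// identical weights, so <A f, g> == <f, At g> to float rounding.

static inline int ray_steps(int H, int W) {
  // cover the full image diagonal; samples outside the grid contribute 0
  double diag = std::sqrt((double)H * H + (double)W * W);
  return (int)std::ceil(diag) + 3;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_forward(NumericMatrix img, NumericVector angles,
                                int n_detectors) {
  const int H = img.nrow(), W = img.ncol();
  const int na = angles.size(), nd = n_detectors;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double dc = (nd - 1) / 2.0;
  const int nt = ray_steps(H, W);
  const double t0 = -(nt - 1) / 2.0;
  NumericMatrix sino(na, nd);
  for (int i = 0; i < na; ++i) {
    const double c = std::cos(angles[i]), s = std::sin(angles[i]);
    for (int j = 0; j < nd; ++j) {
      const double r = j - dc;
      double acc = 0.0;
      for (int k = 0; k < nt; ++k) {
        const double t = t0 + k;
        const double x = r * c - t * s;
        const double y = r * s + t * c;
        const double col = cx + x, row = cy + y;
        const int c0 = (int)std::floor(col), r0 = (int)std::floor(row);
        if (c0 < -1 || c0 > W - 1 || r0 < -1 || r0 > H - 1) continue;
        const double fx = col - c0, fy = row - r0;
        if (r0 >= 0 && c0 >= 0)         acc += (1 - fx) * (1 - fy) * img(r0, c0);
        if (r0 >= 0 && c0 + 1 <= W - 1) acc += fx * (1 - fy) * img(r0, c0 + 1);
        if (r0 + 1 <= H - 1 && c0 >= 0) acc += (1 - fx) * fy * img(r0 + 1, c0);
        if (r0 + 1 <= H - 1 && c0 + 1 <= W - 1)
          acc += fx * fy * img(r0 + 1, c0 + 1);
      }
      sino(i, j) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_adjoint(NumericMatrix sino, NumericVector angles,
                                int H, int W) {
  const int na = sino.nrow(), nd = sino.ncol();
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double dc = (nd - 1) / 2.0;
  const int nt = ray_steps(H, W);
  const double t0 = -(nt - 1) / 2.0;
  NumericMatrix img(H, W);
  for (int i = 0; i < na; ++i) {
    const double c = std::cos(angles[i]), s = std::sin(angles[i]);
    for (int j = 0; j < nd; ++j) {
      const double v = sino(i, j);
      if (v == 0.0) continue;
      const double r = j - dc;
      for (int k = 0; k < nt; ++k) {
        const double t = t0 + k;
        const double x = r * c - t * s;
        const double y = r * s + t * c;
        const double col = cx + x, row = cy + y;
        const int c0 = (int)std::floor(col), r0 = (int)std::floor(row);
        if (c0 < -1 || c0 > W - 1 || r0 < -1 || r0 > H - 1) continue;
        const double fx = col - c0, fy = row - r0;
        if (r0 >= 0 && c0 >= 0)         img(r0, c0) += (1 - fx) * (1 - fy) * v;
        if (r0 >= 0 && c0 + 1 <= W - 1) img(r0, c0 + 1) += fx * (1 - fy) * v;
        if (r0 + 1 <= H - 1 && c0 >= 0) img(r0 + 1, c0) += (1 - fx) * fy * v;
        if (r0 + 1 <= H - 1 && c0 + 1 <= W - 1)
          img(r0 + 1, c0 + 1) += fx * fy * v;
      }
    }
  }
  return img;
}
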