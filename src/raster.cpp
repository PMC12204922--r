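// Software triangle rasterizer with z-buffer, orthographic projection.
// Vertices arrive already projected to pixel coordinates (x right, y down)
// with a depth value where LARGER means closer to the camera.  Per-vertex
// RGB colors are interpolated barycentrically; coverage of any triangle at a
// pixel centre defines the foreground mask (the silhouette pass), so the
// mask is exact regardless of shading.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".rasterize")]]
List rasterize(NumericVector px, NumericVector py, NumericVector pz,
               IntegerMatrix faces, NumericMatrix colors,
               int H, int W, NumericVector bg) {
  NumericVector img(H * W * 3);
  img.attr("dim") = IntegerVector::create(H, W, 3);
  LogicalVector mask(H * W);
  mask.attr("dim") = IntegerVector::create(H, W);
  std::vector<double> zbuf((size_t)H * W, -1e300);
  for (int c = 0; c < 3; ++c)
    for (int p = 0; p < H * W; ++p) img[p + H * W * c] = bg[c];

  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0), b = faces(f, 1), d = faces(f, 2);
    const double x1 = px[a], y1 = py[a], x2 = px[b], y2 = py[b],
                 x3 = px[d], y3 = py[d];
    const double denom = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::fabs(denom) < 1e-12) continue;  // degenerate in projection
    int cmin = std::max(0, (int)std::floor(std::min(x1, std::min(x2, x3)) - 0.5));
    int cmax = std::min(W - 1, (int)std::ceil(std::max(x1, std::max(x2, x3)) - 0.5));
    int rmin = std::max(0, (int)std::floor(std::min(y1, std::min(y2, y3)) - 0.5));
    int rmax = std::min(H - 1, (int)std::ceil(std::max(y1, std::max(y2, y3)) - 0.5));
    for (int r = rmin; r <= rmax; ++r) {
      const double yc = r + 0.5;
      for (int cpx = cmin; cpx <= cmax; ++cpx) {
        const double xc = cpx + 0.5;
        const double l1 = ((y2 - y3) * (xc - x3) + (x3 - x2) * (yc - y3)) / denom;
        const double l2 = ((y3 - y1) * (xc - x3) + (x1 - x3) * (yc - y3)) / denom;
        const double l3 = 1.0 - l1 - l2;
        if (l1 < -1e-9 || l2 < -1e-9 || l3 < -1e-9) continue;
        const double z = l1 * pz[a] + l2 * pz[b] + l3 * pz[d];
        const int p = r + H * cpx;
        mask[p] = true;
        if (z > zbuf[p]) {
          zbuf[p] = z;
          for (int ch = 0; ch < 3; ++ch) {
            double v = l1 * colors(a, ch) + l2 * colors(b, ch) + l3 * colors(d, ch);
            if (v < 0) v = 0; if (v > 1) v = 1;
            img[p + H * W * ch] = v;
          }
        }
      }
    }
  }
  return List::create(_["pixels"] = img, _["mask"] = mask);
}

// Nearest-LUT-color decoding: for each foreground pixel return the index
// (1-based) of the closest LUT entry in RGB space and the distance to it.
// [[Rcpp::export(name = ".nearest_lut")]]
List nearest_lut(NumericVector img, LogicalVector mask, NumericMatrix lut) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const int L = lut.nrow();
  IntegerVector idx(H * W);
  NumericVector dist(H * W);
  idx.attr("dim") = IntegerVector::create(H, W);
  dist.attr("dim") = IntegerVector::create(H, W);
  for (int p = 0; p < H * W; ++p) {
    if (!mask[p]) { idx[p] = NA_INTEGER; dist[p] = NA_REAL; continue; }
    const double r = img[p], g = img[p + H * W], b = img[p + 2 * H * W];
    double best = 1e300; int bi = 0;
    for (int l = 0; l < L; ++l) {
      const double dr = r - lut(l, 0), dg = g - lut(l, 1), db = b - lut(l, 2);
      const double dd = dr * dr + dg * dg + db * db;
      if (dd < best) { best = dd; bi = l; }
    }
    idx[p] = bi + 1;
    dist[p] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
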