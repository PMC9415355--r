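#include <Rcpp.h>
using namespace Rcpp;

// Inside-test for a rotated superellipse body plus line-segment appendages,
// evaluated over a window grid (column-major). Coordinates: x = column
// offset, y = row offset from the body center; the body frame is rotated by
// `angle`. Appendages are segments from the body edge outward with
// half-width `w_half`.
// [[Rcpp::export(name = ".silhouette_window_mask")]]
LogicalVector silhouette_window_mask(NumericVector row_off,
                                     NumericVector col_off,
                                     double angle, double a, double b,
                                     double p, NumericVector app_theta,
                                     double app_len, double w_half) {
  const int nr = row_off.size(), nc = col_off.size();
  LogicalVector inside(nr * nc);
  const double ca = std::cos(angle), sa = std::sin(angle);
  const int napp = app_theta.size();
  // precompute appendage segments in body coordinates
  std::vector<double> p0x(napp), p0y(napp), p1x(napp), p1y(napp), len2(napp);
  for (int k = 0; k < napp; ++k) {
    double t = app_theta[k];
    double er = std::pow(std::fabs(std::cos(t)) / a, p) +
                std::pow(std::fabs(std::sin(t)) / b, p);
    double edge = std::pow(er, -1.0 / p);
    p0x[k] = edge * std::cos(t);
    p0y[k] = edge * std::sin(t);
    p1x[k] = (edge + app_len) * std::cos(t);
    p1y[k] = (edge + app_len) * std::sin(t);
    double dx = p1x[k] - p0x[k], dy = p1y[k] - p0y[k];
    len2[k] = dx * dx + dy * dy;
  }
  const double qmax_body = std::pow(2.0, (p - 2.0) / p);
  const double ring_out = (1.0 + (app_len + w_half) / b);
  const double qmax_ring = ring_out * ring_out;
  const double w2 = w_half * w_half;
  int idx = 0;
  for (int j = 0; j < nc; ++j) {
    const double dx = col_off[j];
    for (int i = 0; i < nr; ++i, ++idx) {
      const double dy = row_off[i];
      const double u = ca * dx + sa * dy;
      const double v = -sa * dx + ca * dy;
      const double qu = u / a, qv = v / b;
      const double q = qu * qu + qv * qv;
      if (q <= 1.0) { inside[idx] = true; continue; }
      if (q <= qmax_body + 1e-9) {
        if (std::pow(std::fabs(qu), p) + std::pow(std::fabs(qv), p) <= 1.0) {
          inside[idx] = true;
          continue;
        }
      }
      if (napp > 0 && q <= qmax_ring) {
        for (int k = 0; k < napp; ++k) {
          double tt = ((u - p0x[k]) * (p1x[k] - p0x[k]) +
                       (v - p0y[k]) * (p1y[k] - p0y[k])) / len2[k];
          tt = tt < 0 ? 0 : (tt > 1 ? 1 : tt);
          const double ex = u - (p0x[k] + tt * (p1x[k] - p0x[k]));
          const double ey = v - (p0y[k] + tt * (p1y[k] - p0y[k]));
          if (ex * ex + ey * ey <= w2) { inside[idx] = true; break; }
        }
      }
    }
  }
  return inside;
}

// Clamp a numeric vector to [0, 1] in place (the caller owns the vector).
// [[Rcpp::export(name = ".clamp01")]]
NumericVector clamp01(NumericVector x) {
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (x[i] < 0) x[i] = 0;
    else if (x[i] > 1) x[i] = 1;
  }
  return x;
}

// 256-bin histogram of intensities in [0, 1] (bin = floor(v * 256), with
// v = 1 folded into the last bin).
// [[Rcpp::export(name = ".hist256")]]
IntegerVector hist256(NumericVector v) {
  IntegerVector counts(256);
  const int n = v.size();
  for (int i = 0; i < n; ++i) {
    int b = (int)(v[i] * 256.0);
    if (b > 255) b = 255;
    counts[b]++;
  }
  return counts;
}

// Connected-component labelling of a logical matrix by flood fill.
// `connectivity` is 4 or 8. Labels are assigned in column-major scan order
// starting at 1; 0 marks background.
// [[Rcpp::export(name = ".label_mask")]]
IntegerMatrix label_mask(LogicalMatrix m, int connectivity) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int pos = stack.back();
        stack.pop_back();
        const int ci = pos % nr, cj = pos / nr;
        for (int k = 0; k < nnb; ++k) {
          const int ni = ci + dr8[k], nj = cj + dc8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (m(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
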