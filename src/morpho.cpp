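#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Greyscale morphological reconstruction by erosion of `marker` above `mask`
// (marker >= mask pointwise), 8-connectivity. Hybrid algorithm: one forward
// and one backward raster sweep followed by FIFO propagation.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erosion(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix f = clone(marker);
  NumericMatrix g = mask;

  // neighbour offsets: N+ (already visited in forward raster order), N- for backward
  const int dpr[4] = {-1,  0, -1, -1};
  const int dpc[4] = { 0, -1, -1,  1};
  const int dmr[4] = { 1,  0,  1,  1};
  const int dmc[4] = { 0,  1,  1, -1};

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = f(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dpr[k], cc = c + dpc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && f(rr, cc) < v) v = f(rr, cc);
      }
      f(r, c) = std::max(v, g(r, c));
    }
  }

  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = f(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dmr[k], cc = c + dmc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && f(rr, cc) < v) v = f(rr, cc);
      }
      f(r, c) = std::max(v, g(r, c));
      for (int k = 0; k < 4; ++k) {
        int rr = r + dmr[k], cc = c + dmc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            f(rr, cc) > f(r, c) && f(rr, cc) > g(rr, cc)) {
          fifo.push(r + nr * c);
          break;
        }
      }
    }
  }

  const int d8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int d8c[8] = {-1,  0,  1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    double fp = f(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + d8r[k], cc = c + d8c[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (f(rr, cc) > fp && f(rr, cc) != g(rr, cc)) {
        f(rr, cc) = std::max(fp, g(rr, cc));
        fifo.push(rr + nr * cc);
      }
    }
  }
  return f;
}

static inline double seg_dist2(double px, double py, double ax, double ay,
                               double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double ex = ax + t * dx - px, ey = ay + t * dy - py;
  return ex * ex + ey * ey;
}

// Minimal Euclidean distance from each query point to the boundary (edges) of
// the closed polygon (px, py); last vertex implicitly joins the first.
// [[Rcpp::export]]
NumericVector cpp_dist_to_boundary(NumericVector x, NumericVector y,
                                   NumericVector px, NumericVector py) {
  int n = x.size(), m = px.size();
  if (m < 3) stop("polygon needs at least 3 vertices");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      int j2 = (j + 1) % m;
      double d2 = seg_dist2(x[i], y[i], px[j], py[j], px[j2], py[j2]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Asymmetry objective: for each rotation angle, rotate (vx, vy) about the
// origin and sum the minimal distances of the rotated vertices to the
// boundary of the fixed polygon (px, py).
// [[Rcpp::export]]
NumericVector cpp_asymmetry_rotations(NumericVector vx, NumericVector vy,
                                      NumericVector px, NumericVector py,
                                      NumericVector angles) {
  int n = vx.size(), m = px.size(), na = angles.size();
  if (m < 3) stop("polygon needs at least 3 vertices");
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double rx = ca * vx[i] - sa * vy[i];
      double ry = sa * vx[i] + ca * vy[i];
      double best = R_PosInf;
      for (int j = 0; j < m; ++j) {
        int j2 = (j + 1) % m;
        double d2 = seg_dist2(rx, ry, px[j], py[j], px[j2], py[j2]);
        if (d2 < best) best = d2;
      }
      s += std::sqrt(best);
    }
    out[a] = s;
  }
  return out;
}

// Even-odd rule point-in-polygon test; points on an edge may go either way
// (callers use cpp_dist_to_boundary for boundary tolerance).
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector x, NumericVector y,
                                   NumericVector px, NumericVector py) {
  int n = x.size(), m = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((py[j] > y[i]) != (py[k] > y[i])) &&
          (x[i] < (px[k] - px[j]) * (y[i] - py[j]) / (py[k] - py[j]) + px[j]))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
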