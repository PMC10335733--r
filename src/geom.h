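#ifndef T6SIM_GEOM_H
#define T6SIM_GEOM_H

#include <cmath>
#include <vector>
#include <algorithm>

namespace t6 {

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// minimum-image wrap of a displacement component into [-L/2, L/2)
inline double min_image(double d, double L) {
  if (L <= 0.0) return d;
  return d - L * std::floor(d / L + 0.5);
}

inline double wrap_coord(double x, double L) {
  return x - L * std::floor(x / L);
}

struct SegDist {
  double d;           // minimum distance between the two segments
  double px, py;      // witness point on segment P
  double qx, qy;      // witness point on segment Q
};

// Closest points between segments P = p1 + s (p2 - p1), Q = q1 + t (q2 - q1),
// s,t in [0,1] (Ericson, Real-Time Collision Detection, ch. 5).
inline SegDist seg_closest(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  const double EPS = 1e-12;
  double d1x = p2x - p1x, d1y = p2y - p1y;
  double d2x = q2x - q1x, d2y = q2y - q1y;
  double rx = p1x - q1x, ry = p1y - q1y;
  double a = d1x * d1x + d1y * d1y;
  double e = d2x * d2x + d2y * d2y;
  double f = d2x * rx + d2y * ry;
  double s, t;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    s = 0.0;
    t = clamp01(f / e);
  } else {
    double c = d1x * rx + d1y * ry;
    if (e <= EPS) {
      t = 0.0;
      s = clamp01(-c / a);
    } else {
      double b = d1x * d2x + d1y * d2y;
      double denom = a * e - b * b;
      s = (denom > EPS) ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = clamp01(-c / a); }
      else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
    }
  }
  SegDist out;
  out.px = p1x + s * d1x; out.py = p1y + s * d1y;
  out.qx = q1x + t * d2x; out.qy = q1y + t * d2y;
  double dx = out.px - out.qx, dy = out.py - out.qy;
  out.d = std::sqrt(dx * dx + dy * dy);
  return out;
}

// Axis endpoints of a spherocylinder: center +/- (ell/2) * (cos th, sin th).
inline void axis_endpoints(double x, double y, double th, double ell,
                           double &x1, double &y1, double &x2, double &y2) {
  double hx = 0.5 * ell * std::cos(th), hy = 0.5 * ell * std::sin(th);
  x1 = x - hx; y1 = y - hy;
  x2 = x + hx; y2 = y + hy;
}

// Segment-segment distance between the axes of cells i and j, with the
// minimum-image convention applied to cell j when periodic. Witness points
// are reported in cell i's frame (cell j possibly shifted by a lattice vector).
inline SegDist cell_axis_dist(double xi, double yi, double thi, double elli,
                              double xj, double yj, double thj, double ellj,
                              double Lx, double Ly, bool periodic) {
  double dx = xj - xi, dy = yj - yi;
  if (periodic) { dx = min_image(dx, Lx); dy = min_image(dy, Ly); }
  double xjs = xi + dx, yjs = yi + dy;
  double a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y;
  axis_endpoints(xi, yi, thi, elli, a1x, a1y, a2x, a2y);
  axis_endpoints(xjs, yjs, thj, ellj, b1x, b1y, b2x, b2y);
  return seg_closest(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y);
}

// Uniform spatial binning over a rectangle; returns candidate pairs (i < j)
// whose axis segments could be within `cutoff` of each other surface-to-surface.
struct PairHit {
  int i, j;
  double d;                   // axis-axis distance
  double px, py, qx, qy;      // witness points (i frame)
};

inline void candidate_pairs(const std::vector<double> &x,
                            const std::vector<double> &y,
                            const std::vector<double> &th,
                            const std::vector<double> &ell,
                            double radius, double Lx, double Ly, bool periodic,
                            double cutoff, std::vector<PairHit> &out) {
  out.clear();
  int n = (int)x.size();
  if (n < 2) return;
  double maxlen = 0.0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, ell[i]);
  // centers further apart than this cannot interact
  double rcut = maxlen + 2.0 * radius + cutoff;

  double ox = 0.0, oy = 0.0, Wx = Lx, Wy = Ly;
  if (!periodic) {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    ox = xmin - 1e-9; oy = ymin - 1e-9;
    Wx = (xmax - xmin) + 2e-9; Wy = (ymax - ymin) + 2e-9;
  }
  int nbx = std::max(1, (int)std::floor(Wx / rcut));
  int nby = std::max(1, (int)std::floor(Wy / rcut));
  if (periodic && (nbx < 3 || nby < 3)) { nbx = 1; nby = 1; }
  double bx = Wx / nbx, by = Wy / nby;
  int nbins = nbx * nby;
  bool allpairs = nbins < 9;

  // precompute axis endpoints once (keeps trig out of the pair loop)
  std::vector<double> e1x(n), e1y(n), e2x(n), e2y(n);
  for (int i = 0; i < n; ++i) {
    double hx = 0.5 * ell[i] * std::cos(th[i]);
    double hy = 0.5 * ell[i] * std::sin(th[i]);
    e1x[i] = x[i] - hx; e1y[i] = y[i] - hy;
    e2x[i] = x[i] + hx; e2y[i] = y[i] + hy;
  }

  auto test_pair = [&](int i, int j) {
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double sx = 0.0, sy = 0.0;
    if (periodic) {
      double wx = min_image(dx, Lx), wy = min_image(dy, Ly);
      sx = wx - dx; sy = wy - dy;   // lattice shift applied to cell j
      dx = wx; dy = wy;
    }
    double rr = 0.5 * (ell[i] + ell[j]) + 2.0 * radius + cutoff;
    if (dx * dx + dy * dy > rr * rr) return;
    SegDist sd = seg_closest(e1x[i], e1y[i], e2x[i], e2y[i],
                             e1x[j] + sx, e1y[j] + sy,
                             e2x[j] + sx, e2y[j] + sy);
    if (sd.d - 2.0 * radius <= cutoff)
      out.push_back(PairHit{i, j, sd.d, sd.px, sd.py, sd.qx, sd.qy});
  };

  if (allpairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) test_pair(i, j);
    return;
  }

  // counting sort of cell indices by bin for contiguous traversal
  std::vector<int> count(nbins + 1, 0), binof(n), order(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i] - ox, yi = y[i] - oy;
    if (periodic) { xi = wrap_coord(x[i], Lx); yi = wrap_coord(y[i], Ly); }
    int cx = std::min(nbx - 1, std::max(0, (int)(xi / bx)));
    int cy = std::min(nby - 1, std::max(0, (int)(yi / by)));
    binof[i] = cy * nbx + cx;
    ++count[binof[i] + 1];
  }
  for (int b = 0; b < nbins; ++b) count[b + 1] += count[b];
  {
    std::vector<int> cursor(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[binof[i]]++] = i;
  }

  // forward half-stencil: self, E, NW, N, NE (each unordered pair once)
  const int offs[5][2] = {{0, 0}, {1, 0}, {-1, 1}, {0, 1}, {1, 1}};
  for (int cy = 0; cy < nby; ++cy) {
    for (int cx = 0; cx < nbx; ++cx) {
      int b = cy * nbx + cx;
      int b0 = count[b], b1 = count[b + 1];
      if (b0 == b1) continue;
      for (int s = 0; s < 5; ++s) {
        int nx = cx + offs[s][0], ny = cy + offs[s][1];
        if (periodic) {
          nx = (nx + nbx) % nbx; ny = (ny + nby) % nby;
        } else if (nx < 0 || nx >= nbx || ny >= nby) {
          continue;
        }
        int nb = ny * nbx + nx;
        int c0 = count[nb], c1 = count[nb + 1];
        if (s == 0) {
          for (int a = b0; a < b1; ++a)
            for (int c = a + 1; c < b1; ++c)
              test_pair(order[a], order[c]);
        } else {
          if (nb == b) continue; // tiny periodic grids fold onto self
          for (int a = b0; a < b1; ++a)
            for (int c = c0; c < c1; ++c)
              test_pair(order[a], order[c]);
        }
      }
    }
  }
}

} // namespace t6

#endif
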