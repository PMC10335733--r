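#include <Rcpp.h>
#include "geom.h"
using namespace Rcpp;

// Minimum distance between 2D segments (a1,a2) and (b1,b2), with the
// minimum-image convention applied to segment b when periodic.
// Vectorised over rows. Returns distance and witness points.
// [[Rcpp::export]]
List seg_min_dist_cpp(NumericMatrix a1, NumericMatrix a2,
                      NumericMatrix b1, NumericMatrix b2,
                      double Lx, double Ly, bool periodic) {
  int n = a1.nrow();
  NumericVector d(n), px(n), py(n), qx(n), qy(n);
  for (int i = 0; i < n; ++i) {
    double b1x = b1(i, 0), b1y = b1(i, 1), b2x = b2(i, 0), b2y = b2(i, 1);
    if (periodic) {
      // shift segment b by the minimum image of its midpoint offset
      double amx = 0.5 * (a1(i, 0) + a2(i, 0)), amy = 0.5 * (a1(i, 1) + a2(i, 1));
      double bmx = 0.5 * (b1x + b2x), bmy = 0.5 * (b1y + b2y);
      double sx = t6::min_image(bmx - amx, Lx) - (bmx - amx);
      double sy = t6::min_image(bmy - amy, Ly) - (bmy - amy);
      b1x += sx; b2x += sx; b1y += sy; b2y += sy;
    }
    t6::SegDist sd = t6::seg_closest(a1(i, 0), a1(i, 1), a2(i, 0), a2(i, 1),
                                     b1x, b1y, b2x, b2y);
    d[i] = sd.d; px[i] = sd.px; py[i] = sd.py; qx[i] = sd.qx; qy[i] = sd.qy;
  }
  return List::create(_["distance"] = d, _["px"] = px, _["py"] = py,
                      _["qx"] = qx, _["qy"] = qy);
}

// All cell pairs whose surface gap (axis distance - 2 radius) is <= cutoff,
// found by uniform spatial binning. Columns: i, j (1-based), axis distance,
// witness points on i and j (i's frame under minimum image).
// [[Rcpp::export]]
NumericMatrix cell_pairs_cpp(NumericVector x, NumericVector y,
                             NumericVector theta, NumericVector ell,
                             double radius, double Lx, double Ly,
                             bool periodic, double cutoff) {
  int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<double> vth(theta.begin(), theta.end()), vell(ell.begin(), ell.end());
  std::vector<t6::PairHit> hits;
  t6::candidate_pairs(vx, vy, vth, vell, radius, Lx, Ly, periodic, cutoff, hits);
  NumericMatrix out((int)hits.size(), 7);
  for (int k = 0; k < (int)hits.size(); ++k) {
    out(k, 0) = hits[k].i + 1;
    out(k, 1) = hits[k].j + 1;
    out(k, 2) = hits[k].d;
    out(k, 3) = hits[k].px; out(k, 4) = hits[k].py;
    out(k, 5) = hits[k].qx; out(k, 6) = hits[k].qy;
  }
  colnames(out) = CharacterVector::create("i", "j", "distance",
                                          "pxi", "pyi", "pxj", "pyj");
  return out;
}

// Net elastic contact forces and torques on each cell from Hookean overlap
// repulsion between spherocylinder surfaces. Returns per-cell fx, fy, torque
// and the per-cell sum of positive overlaps.
// [[Rcpp::export]]
List contact_forces_cpp(NumericVector x, NumericVector y,
                        NumericVector theta, NumericVector ell,
                        double radius, double Lx, double Ly, bool periodic,
                        double k_elastic) {
  int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<double> vth(theta.begin(), theta.end()), vell(ell.begin(), ell.end());
  std::vector<t6::PairHit> hits;
  t6::candidate_pairs(vx, vy, vth, vell, radius, Lx, Ly, periodic, 0.0, hits);
  NumericVector fx(n), fy(n), tq(n), ovl(n);
  for (auto &h : hits) {
    double delta = 2.0 * radius - h.d;
    if (delta <= 0.0) continue;
    double nx, ny;
    if (h.d > 1e-12) {
      nx = (h.px - h.qx) / h.d; ny = (h.py - h.qy) / h.d;
    } else {
      // coincident axes: deterministic fallback, perpendicular to i's axis
      nx = -std::sin(vth[h.i]); ny = std::cos(vth[h.i]);
    }
    double f = k_elastic * delta;
    fx[h.i] += f * nx; fy[h.i] += f * ny;
    fx[h.j] -= f * nx; fy[h.j] -= f * ny;
    // torque about each cell's center from the force at its witness point
    double cjx = vx[h.i] + (periodic ? t6::min_image(vx[h.j] - vx[h.i], Lx)
                                     : vx[h.j] - vx[h.i]);
    double cjy = vy[h.i] + (periodic ? t6::min_image(vy[h.j] - vy[h.i], Ly)
                                     : vy[h.j] - vy[h.i]);
    tq[h.i] += (h.px - vx[h.i]) * f * ny - (h.py - vy[h.i]) * f * nx;
    tq[h.j] += (h.qx - cjx) * (-f * ny) - (h.qy - cjy) * (-f * nx);
    ovl[h.i] += delta; ovl[h.j] += delta;
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["torque"] = tq,
                      _["overlap_sum"] = ovl);
}

// Rejection-sampled non-overlapping placement of n spherocylinders with
// random orientations, uniform either over the rectangle [0,Lx]x[0,Ly] or
// over a disc. Total length is L0*(1+u), u~U(0,1), with u*L0 recorded as
// the adder progress so the first divisions are desynchronised.
// [[Rcpp::export]]
List place_cells_cpp(int n, double Lx, double Ly, bool periodic,
                     double radius, double L0, bool disc, double ccx,
                     double ccy, double R0, int budget_per_cell) {
  NumericVector x(n), y(n), th(n), ell(n), added(n);
  long budget = (long)budget_per_cell * n;
  int placed = 0;
  while (placed < n && budget > 0) {
    --budget;
    double px, py;
    if (disc) {
      double rr = R0 * std::sqrt(unif_rand());
      double aa = unif_rand() * 2.0 * M_PI;
      px = ccx + rr * std::cos(aa);
      py = ccy + rr * std::sin(aa);
    } else {
      px = unif_rand() * Lx;
      py = unif_rand() * Ly;
    }
    double pth = unif_rand() * 2.0 * M_PI;
    double u = unif_rand();
    double pell = L0 * (1.0 + u) - 2.0 * radius;
    bool ok = true;
    double pr = 0.5 * pell + 2.0 * radius; // center-distance prefilter base
    for (int j = 0; j < placed; ++j) {
      double dx = x[j] - px, dy = y[j] - py;
      if (periodic) { dx = t6::min_image(dx, Lx); dy = t6::min_image(dy, Ly); }
      double rr = pr + 0.5 * ell[j];
      if (dx * dx + dy * dy > rr * rr) continue;
      t6::SegDist sd = t6::cell_axis_dist(px, py, pth, pell, x[j], y[j],
                                          th[j], ell[j], Lx, Ly, periodic);
      if (sd.d <= 2.0 * radius) { ok = false; break; }
    }
    if (!ok) continue;
    x[placed] = px; y[placed] = py; th[placed] = pth;
    ell[placed] = pell; added[placed] = L0 * u;
    ++placed;
  }
  return List::create(_["x"] = x, _["y"] = y, _["theta"] = th,
                      _["ell"] = ell, _["added"] = added,
                      _["placed"] = placed);
}
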