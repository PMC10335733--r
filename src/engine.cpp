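#include <Rcpp.h>
#include "geom.h"
using namespace Rcpp;

// The agent-based competition engine.
//
// Each reaction step of length dt executes, in fixed order:
//   build contact graph -> overdamped mechanics sub-steps -> activation ->
//   sheath synthesis/firing -> firing resolution -> lysis update ->
//   growth with attenuation -> division.
// Placing the mechanics pass directly after the graph build lets it reuse
// the freshly computed pair geometry; it is the trailing mechanics pass of
// the conceptual step rotated to the front, and cells move far less than
// the contact tolerance within one step.
// All randomness is drawn from R's RNG stream, so a set.seed() at the R
// level makes a run bit-identical.
//
// strains: matrix with one row per strain and columns
//   p0, tau_plus, lambda_plus, lambda_s, lambda_f, r_eff, tau_lys, r0
// (activated cells grow at the penalised rate r_eff = max(0, r0 - c
// lambda_s); inactive cells are not yet producing sheaths and grow at r0)
// window: (x0, x1, y0, y1) measurement rectangle for area occupancy.
// k_max: number of firing slots (contacts + void); <= 0 means "no misses
//   whenever at least one contact exists".
// [[Rcpp::export]]
List abm_run_cpp(NumericVector x0v, NumericVector y0v, NumericVector theta0,
                 NumericVector ell0, NumericVector ell_birth0,
                 NumericVector added0, IntegerVector strain0,
                 LogicalVector G0, IntegerVector N0, IntegerVector status0,
                 NumericVector lysis0, IntegerVector id0,
                 NumericMatrix strains, double radius,
                 double Lx, double Ly, bool periodic, double carrying_capacity,
                 double k_elastic, double zeta, double zeta_rot,
                 double contact_eps, double pressure_star, double dt_mech,
                 int k_max, double t_end, double dt, int record_every,
                 double delta_L, double div_angle_sd, NumericVector window,
                 int max_cells) {
  int ns = strains.nrow();
  std::vector<double> p0(ns), taup(ns), lplus(ns), ls(ns), lf(ns), reff(ns),
      tlys(ns), r0(ns);
  for (int s = 0; s < ns; ++s) {
    p0[s] = strains(s, 0); taup[s] = strains(s, 1); lplus[s] = strains(s, 2);
    ls[s] = strains(s, 3); lf[s] = strains(s, 4); reff[s] = strains(s, 5);
    tlys[s] = strains(s, 6); r0[s] = strains(s, 7);
  }

  std::vector<double> x(x0v.begin(), x0v.end()), y(y0v.begin(), y0v.end());
  std::vector<double> th(theta0.begin(), theta0.end()), ell(ell0.begin(), ell0.end());
  std::vector<double> ellb(ell_birth0.begin(), ell_birth0.end());
  std::vector<double> added(added0.begin(), added0.end());
  std::vector<double> lys(lysis0.begin(), lysis0.end());
  std::vector<int> strain(strain0.begin(), strain0.end()); // 1-based
  std::vector<int> N(N0.begin(), N0.end()), status(status0.begin(), status0.end());
  std::vector<int> id(id0.begin(), id0.end());
  std::vector<char> G(G0.size());
  for (int i = 0; i < (int)G0.size(); ++i) G[i] = G0[i] ? 1 : 0;
  int next_id = 0;
  for (size_t i = 0; i < id.size(); ++i) next_id = std::max(next_id, id[i]);
  ++next_id;

  // per-strain step probabilities (dt is constant across the run)
  std::vector<double> p_act(ns), p_birth(ns), p_fire(ns);
  for (int s = 0; s < ns; ++s) {
    p_act[s] = 1.0 - std::exp(-lplus[s] * dt);
    p_birth[s] = ls[s] * dt;
    p_fire[s] = 1.0 - std::exp(-lf[s] * dt);
  }

  int nsteps = (int)std::ceil(t_end / dt - 1e-9);
  int n_sub = std::max(1, (int)std::ceil(dt / dt_mech - 1e-9));
  double dts = dt / n_sub;

  int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec);
  IntegerMatrix rec_live(nrec, ns), rec_lys(nrec, ns);
  NumericMatrix rec_area(nrec, ns);
  NumericVector rec_occ(nrec);
  std::vector<long> kills(ns, 0);
  long births = 0, removed = 0;
  std::string run_status = "ok";

  double wx0 = window[0], wx1 = window[1], wy0 = window[2], wy1 = window[3];
  double arena_area = Lx * Ly;
  double pb_cache_dt = dt; (void)pb_cache_dt;

  std::vector<t6::PairHit> hits;
  std::vector<int> adj_off, adj_nbr, adj_cur;
  std::vector<double> ovl;

  auto record = [&](int slot, double t) {
    rec_t[slot] = t;
    double occ = 0.0;
    std::vector<double> area(ns, 0.0);
    std::vector<int> nl(ns, 0), nz(ns, 0);
    for (size_t i = 0; i < x.size(); ++i) {
      double a = 2.0 * radius * ell[i] + M_PI * radius * radius;
      occ += a;
      int s = strain[i] - 1;
      if (status[i] == 0) {
        ++nl[s];
        double cx = x[i], cy = y[i];
        if (periodic) { cx = t6::wrap_coord(cx, Lx); cy = t6::wrap_coord(cy, Ly); }
        if (cx >= wx0 && cx <= wx1 && cy >= wy0 && cy <= wy1) area[s] += a;
      } else {
        ++nz[s];
      }
    }
    for (int s = 0; s < ns; ++s) {
      rec_live(slot, s) = nl[s]; rec_lys(slot, s) = nz[s];
      rec_area(slot, s) = area[s];
    }
    rec_occ[slot] = occ / arena_area;
  };
  record(0, 0.0);

  int rec_slot = 1;
  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    int n = (int)x.size();
    if (n == 0) { run_status = "extinct"; break; }
    if (n > max_cells) { run_status = "overflow"; break; }

    // 1. contact graph (CSR layout) and per-cell overlap pressure
    t6::candidate_pairs(x, y, th, ell, radius, Lx, Ly, periodic, contact_eps, hits);
    adj_off.assign(n + 1, 0);
    ovl.assign(n, 0.0);
    for (auto &h : hits) {
      double gap = h.d - 2.0 * radius;
      if (gap <= contact_eps) { ++adj_off[h.i + 1]; ++adj_off[h.j + 1]; }
      if (gap < 0.0) { ovl[h.i] -= gap; ovl[h.j] -= gap; }
    }
    for (int i = 0; i < n; ++i) adj_off[i + 1] += adj_off[i];
    adj_nbr.resize(adj_off[n]);
    adj_cur.assign(adj_off.begin(), adj_off.end() - 1);
    for (auto &h : hits) {
      if (h.d - 2.0 * radius <= contact_eps) {
        adj_nbr[adj_cur[h.i]++] = h.j;
        adj_nbr[adj_cur[h.j]++] = h.i;
      }
    }

    // 2. overdamped mechanics, reusing the pair geometry just computed
    // (this is the trailing mechanics pass of the conceptual step, applied
    // while the freshly built graph is exact; cells move far less than the
    // contact tolerance within one step, so the graph stays valid for the
    // firing resolution below). Lysing cells participate fully.
    {
      double max_disp2_allowed = 0.25 * radius * radius;
      bool unstable = false;
      for (int sub = 0; sub < n_sub && !unstable; ++sub) {
        std::vector<double> fx(n, 0.0), fy(n, 0.0), tq(n, 0.0);
        for (auto &h : hits) {
          double d = h.d, pxw = h.px, pyw = h.py, qxw = h.qx, qyw = h.qy;
          if (sub > 0) {
            t6::SegDist sd = t6::cell_axis_dist(
                x[h.i], y[h.i], th[h.i], ell[h.i],
                x[h.j], y[h.j], th[h.j], ell[h.j], Lx, Ly, periodic);
            d = sd.d; pxw = sd.px; pyw = sd.py; qxw = sd.qx; qyw = sd.qy;
          }
          double delta = 2.0 * radius - d;
          if (delta <= 0.0) continue;
          double nx, ny;
          if (d > 1e-12) { nx = (pxw - qxw) / d; ny = (pyw - qyw) / d; }
          else { nx = -std::sin(th[h.i]); ny = std::cos(th[h.i]); }
          double f = k_elastic * delta;
          fx[h.i] += f * nx; fy[h.i] += f * ny;
          fx[h.j] -= f * nx; fy[h.j] -= f * ny;
          double cjx = x[h.i] + (periodic ? t6::min_image(x[h.j] - x[h.i], Lx)
                                          : x[h.j] - x[h.i]);
          double cjy = y[h.i] + (periodic ? t6::min_image(y[h.j] - y[h.i], Ly)
                                          : y[h.j] - y[h.i]);
          tq[h.i] += (pxw - x[h.i]) * f * ny - (pyw - y[h.i]) * f * nx;
          tq[h.j] += (qxw - cjx) * (-f) * ny - (qyw - cjy) * (-f) * nx;
        }
        for (int i = 0; i < n; ++i) {
          double Ltot = ell[i] + 2.0 * radius;
          double dx = fx[i] / (zeta * Ltot) * dts;
          double dy = fy[i] / (zeta * Ltot) * dts;
          if (dx * dx + dy * dy > max_disp2_allowed) { unstable = true; break; }
          x[i] += dx; y[i] += dy;
          th[i] += tq[i] / (zeta_rot * Ltot * Ltot * Ltot) * dts;
          if (periodic) {
            x[i] = t6::wrap_coord(x[i], Lx);
            y[i] = t6::wrap_coord(y[i], Ly);
          }
        }
      }
      if (unstable) { run_status = "unstable"; break; }
    }

    // 3. internal reactions and firing resolution
    for (int i = 0; i < n; ++i) {
      if (status[i] != 0) continue;
      int s = strain[i] - 1;
      if (!G[i]) {
        if (lplus[s] > 0.0 && t >= taup[s] - 1e-12 &&
            unif_rand() < p_act[s])
          G[i] = 1;
        continue;
      }
      // firing of existing sheaths, then synthesis with midpoint exposure
      // (a sheath born within the step sees half a step of firing)
      int fired = 0;
      if (lf[s] > 0.0 && N[i] > 0) {
        fired = (int)R::rbinom((double)N[i], p_fire[s]);
        N[i] -= fired;
      }
      if (ls[s] > 0.0 && unif_rand() < p_birth[s]) {
        if (lf[s] > 0.0 && unif_rand() < 0.5 * p_fire[s]) ++fired;
        else ++N[i];
      }
      if (fired == 0) continue;
      int k = adj_off[i + 1] - adj_off[i];
      int slots = (k_max > 0) ? std::max(k, k_max) : std::max(k, 1);
      for (int f = 0; f < fired; ++f) {
        int u = (int)(unif_rand() * slots);
        if (u >= slots) u = slots - 1;
        if (u >= k) continue; // fired into the void
        int tgt = adj_nbr[adj_off[i] + u];
        if (strain[tgt] == strain[i]) continue; // clonemate immunity
        if (status[tgt] != 0) continue;         // corpse absorbs the hit
        status[tgt] = 1;
        lys[tgt] = tlys[strain[tgt] - 1];
        ++kills[strain[tgt] - 1];
      }
    }

    // 4. lysis countdown and removal
    {
      int w = 0;
      for (int i = 0; i < n; ++i) {
        if (status[i] == 1) {
          lys[i] -= dt;
          if (lys[i] <= 1e-12) { ++removed; continue; }
        }
        if (w != i) {
          x[w] = x[i]; y[w] = y[i]; th[w] = th[i]; ell[w] = ell[i];
          ellb[w] = ellb[i]; added[w] = added[i]; lys[w] = lys[i];
          strain[w] = strain[i]; N[w] = N[i]; status[w] = status[i];
          id[w] = id[i]; G[w] = G[i]; ovl[w] = ovl[i];
        }
        ++w;
      }
      x.resize(w); y.resize(w); th.resize(w); ell.resize(w); ellb.resize(w);
      added.resize(w); lys.resize(w); strain.resize(w); N.resize(w);
      status.resize(w); id.resize(w); G.resize(w); ovl.resize(w);
      n = w;
    }

    // 5. growth (exponential elongation, attenuated by local pressure and
    //    the global carrying capacity)
    double occ = 0.0;
    for (int i = 0; i < n; ++i)
      occ += 2.0 * radius * ell[i] + M_PI * radius * radius;
    occ /= arena_area;
    double cap_att = std::max(0.0, 1.0 - occ / carrying_capacity);
    if (cap_att > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (status[i] != 0) continue;
        double r = G[i] ? reff[strain[i] - 1] : r0[strain[i] - 1];
        if (r <= 0.0) continue;
        double att = std::max(0.0, 1.0 - ovl[i] / pressure_star) * cap_att;
        if (att <= 0.0) continue;
        double Ltot = ell[i] + 2.0 * radius;
        double Lnew = Ltot * std::exp(r * att * dt);
        added[i] += Lnew - Ltot;
        ell[i] += Lnew - Ltot;
      }
    }

    // 6. division (adder rule: divide after adding delta_L since birth)
    for (int i = 0; i < n; ++i) {
      if (status[i] != 0 || added[i] < delta_L) continue;
      double Ltot = ell[i] + 2.0 * radius;
      double elld = std::max(0.0, 0.5 * (ell[i] - 2.0 * radius));
      double ux = std::cos(th[i]), uy = std::sin(th[i]);
      double off = 0.25 * Ltot;
      int n1 = (N[i] > 0) ? (int)R::rbinom((double)N[i], 0.5) : 0;
      int n2 = N[i] - n1;
      double xm = x[i], ym = y[i], thm = th[i];
      // first daughter replaces the mother in place
      x[i] = xm - off * ux; y[i] = ym - off * uy;
      th[i] = thm + norm_rand() * div_angle_sd;
      ell[i] = elld; ellb[i] = elld; added[i] = 0.0; N[i] = n1;
      // second daughter appended
      x.push_back(xm + off * ux); y.push_back(ym + off * uy);
      th.push_back(thm + norm_rand() * div_angle_sd);
      ell.push_back(elld); ellb.push_back(elld); added.push_back(0.0);
      lys.push_back(0.0); strain.push_back(strain[i]); N.push_back(n2);
      status.push_back(0); id.push_back(next_id++); G.push_back(G[i]);
      ovl.push_back(ovl[i]);
      if (periodic) {
        x[i] = t6::wrap_coord(x[i], Lx); y[i] = t6::wrap_coord(y[i], Ly);
        x.back() = t6::wrap_coord(x.back(), Lx);
        y.back() = t6::wrap_coord(y.back(), Ly);
      }
      ++births;
    }
    n = (int)x.size();

    if ((step + 1) % record_every == 0 && rec_slot < nrec)
      record(rec_slot++, (step + 1) * dt);
  }
  // pad unreached record slots (early termination)
  for (; rec_slot < nrec; ++rec_slot) {
    rec_t[rec_slot] = NA_REAL;
    for (int s = 0; s < ns; ++s) {
      rec_live(rec_slot, s) = NA_INTEGER; rec_lys(rec_slot, s) = NA_INTEGER;
      rec_area(rec_slot, s) = NA_REAL;
    }
    rec_occ[rec_slot] = NA_REAL;
  }

  int n = (int)x.size();
  LogicalVector Gout(n);
  for (int i = 0; i < n; ++i) Gout[i] = G[i] != 0;
  DataFrame cells = DataFrame::create(
      _["id"] = IntegerVector(id.begin(), id.end()),
      _["strain"] = IntegerVector(strain.begin(), strain.end()),
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["theta"] = NumericVector(th.begin(), th.end()),
      _["ell"] = NumericVector(ell.begin(), ell.end()),
      _["ell_birth"] = NumericVector(ellb.begin(), ellb.end()),
      _["added"] = NumericVector(added.begin(), added.end()),
      _["G"] = Gout,
      _["N"] = IntegerVector(N.begin(), N.end()),
      _["status"] = IntegerVector(status.begin(), status.end()),
      _["lysis_clock"] = NumericVector(lys.begin(), lys.end()));

  return List::create(
      _["times"] = rec_t, _["live"] = rec_live, _["lysing"] = rec_lys,
      _["area"] = rec_area, _["occupancy"] = rec_occ,
      _["kills"] = NumericVector(kills.begin(), kills.end()),
      _["births"] = (double)births, _["removed"] = (double)removed,
      _["cells"] = cells, _["status"] = run_status);
}
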