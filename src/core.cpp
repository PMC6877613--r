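// Core numerics for the rod-suspension simulator:
//  - screened Hele-Shaw kernel (tabulated, linear interpolation in z = sqrt(kappa)*|r|)
//  - spherocylinder segment-segment contact geometry with minimal-image convention
//  - Euler integration of the coupled position/orientation/pathway dynamics
// All physical units: micrometres, seconds, piconewtons (eta in pN s / um^2).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;

struct Kernel {
  // c1, c2 tabulated on a uniform z grid [zmin, zmin + dz*(nz-1)]
  double zmin, dz, zmax;
  const double *c1, *c2;
  int nz;
  double kappa, sqrtk, pref; // pref = 1/(pi*eta*h*kappa)
  double r_clamp, r_cutoff;

  inline void factors(double z, double &f1, double &f2) const {
    if (z <= zmin) z = zmin;
    if (z >= zmax) { f1 = c1[nz - 1]; f2 = c2[nz - 1]; return; }
    double u = (z - zmin) / dz;
    int i = (int)u; if (i > nz - 2) i = nz - 2;
    double w = u - i;
    f1 = c1[i] * (1.0 - w) + c1[i + 1] * w;
    f2 = c2[i] * (1.0 - w) + c2[i + 1] * w;
  }

  // G(r) entries; returns false outside cutoff or for exactly coincident points
  inline bool tensor(double rx, double ry, double &gxx, double &gxy, double &gyy) const {
    double r2 = rx * rx + ry * ry;
    double r = std::sqrt(r2);
    if (r > r_cutoff) return false;
    if (r < 1e-12) return false; // self/coincident: excluded upstream
    if (r < r_clamp) { // clamped near-field evaluation, same direction
      double s = r_clamp / r;
      rx *= s; ry *= s; r = r_clamp; r2 = r * r;
    }
    double f1, f2;
    factors(sqrtk * r, f1, f2);
    double p = pref / r2;
    double ux = rx / r, uy = ry / r;
    gxx = p * (f1 + f2 * ux * ux);
    gxy = p * (f2 * ux * uy);
    gyy = p * (f1 + f2 * uy * uy);
    return true;
  }
};

static inline double pimage(double d, double box) {
  // minimal image of a coordinate difference
  if (d > 0.5 * box) d -= box;
  else if (d < -0.5 * box) d += box;
  return d;
}

// Closest points between two segments centred at the origin-shifted pair.
// Segment i: s in [-ai, ai] along (nx1, ny1) from centre 1 (taken as origin);
// segment j: t in [-aj, aj] along (nx2, ny2) from centre 2 at (dx, dy).
// Returns squared distance; s and t hold the closest-point parameters.
static double seg_seg(double dx, double dy, double nx1, double ny1, double a1,
                      double nx2, double ny2, double a2, double &s, double &t) {
  // Solve min |s*n1 - (d + t*n2)|^2 over the parameter box.
  double b = nx1 * nx2 + ny1 * ny2;          // n1.n2
  double f = dx * nx2 + dy * ny2;            // d.n2
  double c = dx * nx1 + dy * ny1;            // d.n1
  double denom = 1.0 - b * b;
  if (denom > 1e-9) {
    s = (c - b * f) / denom;
    if (s > a1) s = a1; else if (s < -a1) s = -a1;
  } else {
    // parallel rods: centre of the overlap interval (symmetric, torque-consistent)
    double lo = std::max(-a1, c - a2), hi = std::min(a1, c + a2);
    if (lo > hi) s = (lo + hi) * 0.5; // disjoint projections: midpoint still defined
    else s = (lo + hi) * 0.5;
    if (s > a1) s = a1; else if (s < -a1) s = -a1;
  }
  t = s * b - f;
  if (t > a2) t = a2; else if (t < -a2) t = -a2;
  // re-clamp s against chosen t
  s = t * b + c;
  if (s > a1) s = a1; else if (s < -a1) s = -a1;
  double px = s * nx1 - dx - t * nx2;
  double py = s * ny1 - dy - t * ny2;
  return px * px + py * py;
}

// Exported contact search (brute force over a cell list), used by find_contacts()
// and internally each time step.  Columns of the returned matrix:
// i, j (1-based), delta, ux, uy, cx, cy (contact point rel. to centre i, minimal image),
// si, tj (closest point parameters along each rod axis), d
static void contacts_impl(const std::vector<double> &x, const std::vector<double> &y,
                          const std::vector<double> &th, double L, double e, double box,
                          std::vector<double> &out) {
  int n = (int)x.size();
  double a = 0.5 * (L - e);     // half-length of the core segment
  double cut = L;               // max centre distance for possible contact
  out.clear();
  int nb = (int)std::floor(box / cut); if (nb < 1) nb = 1;
  double bw = box / nb;
  bool all_pairs = nb < 4;
  std::vector<int> head, nxt(n);
  std::vector<int> binof(n);
  if (!all_pairs) {
    head.assign(nb * nb, -1);
    for (int i = 0; i < n; ++i) {
      int bx = (int)(x[i] / bw) % nb, by = (int)(y[i] / bw) % nb;
      if (bx < 0) bx += nb; if (by < 0) by += nb;
      int b = by * nb + bx;
      binof[i] = b; nxt[i] = head[b]; head[b] = i;
    }
  }
  double cut2 = cut * cut;
  auto test_pair = [&](int i, int j) {
    double dx = pimage(x[j] - x[i], box), dy = pimage(y[j] - y[i], box);
    if (dx * dx + dy * dy > cut2) return;
    double n1x = std::cos(th[i]), n1y = std::sin(th[i]);
    double n2x = std::cos(th[j]), n2y = std::sin(th[j]);
    double s, t;
    double d2 = seg_seg(dx, dy, n1x, n1y, a, n2x, n2y, a, s, t);
    double d = std::sqrt(d2);
    if (d >= e) return;
    double ux, uy;
    if (d > 1e-9) {
      // normal pointing from j's closest point towards i's closest point
      ux = (s * n1x - dx - t * n2x) / d;
      uy = (s * n1y - dy - t * n2y) / d;
    } else { // coincident axes: push perpendicular to rod i
      ux = -n1y; uy = n1x;
    }
    double p1x = s * n1x, p1y = s * n1y;             // on axis of i (rel. centre i)
    double p2x = dx + t * n2x, p2y = dy + t * n2y;   // on axis of j (rel. centre i)
    double cx = 0.5 * (p1x + p2x), cy = 0.5 * (p1y + p2y);
    double delta = e - d;
    double row[10] = {(double)(i + 1), (double)(j + 1), delta, ux, uy, cx, cy, s, t, d};
    out.insert(out.end(), row, row + 10);
  };
  if (all_pairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) test_pair(i, j);
  } else {
    for (int i = 0; i < n; ++i) {
      int bx = binof[i] % nb, by = binof[i] / nb;
      for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
        int cx2 = (bx + ox + nb) % nb, cy2 = (by + oy + nb) % nb;
        for (int j = head[cy2 * nb + cx2]; j >= 0; j = nxt[j])
          if (j > i) test_pair(i, j);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_find_contacts(NumericVector x, NumericVector y, NumericVector theta,
                                double L, double e, double box) {
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end()),
      tt(theta.begin(), theta.end()), out;
  contacts_impl(xx, yy, tt, L, e, box, out);
  int nc = (int)out.size() / 10;
  NumericMatrix m(nc, 10);
  for (int r = 0; r < nc; ++r)
    for (int cI = 0; cI < 10; ++cI) m(r, cI) = out[r * 10 + cI];
  colnames(m) = CharacterVector::create("i", "j", "delta", "ux", "uy",
                                        "cx", "cy", "si", "tj", "d");
  return m;
}

struct SimPar {
  int n;
  double box, L, e, Ldip, eta, Kel, Kfr;
  double gpar, gperp, grot;
  double Dr, DT, tau_t;
  bool hydro, steric, gate_dipole;
  int hydro_every;
  // pathway
  double Nrec, Koff, Kon, eps0, eps1, kR, kB, Hmot, lambda0, m_max, a_ss;
  double c_mid, grad, x0;
  Kernel ker;
};

struct SimState {
  std::vector<double> x, y, ux_unw, th, v0, m, timer, velx, vely;
  std::vector<int> motor;
};

// hydrodynamic flow cache
struct Flows {
  std::vector<double> wmx, wmy, wrot;
};

static void compute_flows(const SimPar &P, const SimState &S, Flows &F) {
  int n = P.n;
  F.wmx.assign(n, 0.0); F.wmy.assign(n, 0.0); F.wrot.assign(n, 0.0);
  if (!P.hydro) return;
  double box = P.box;
  double cut = P.ker.r_cutoff + P.Ldip;
  double cut2 = cut * cut;
  std::vector<double> nx(n), ny(n), Fx(n), Fy(n);
  std::vector<double> wAx(n, 0.0), wAy(n, 0.0), wBx(n, 0.0), wBy(n, 0.0);
  for (int i = 0; i < n; ++i) {
    nx[i] = std::cos(S.th[i]); ny[i] = std::sin(S.th[i]);
    double on = (S.motor[i] == 1 || !P.gate_dipole) ? 1.0 : 0.0;
    Fx[i] = on * P.gpar * S.v0[i] * nx[i];
    Fy[i] = on * P.gpar * S.v0[i] * ny[i];
  }
  // cell list on centres (fall back to all pairs for large cutoff)
  int nb = (int)std::floor(box / cut); if (nb < 1) nb = 1;
  bool all_pairs = nb < 4;
  double bw = box / nb;
  std::vector<int> head, nxt(n), binof(n);
  if (!all_pairs) {
    head.assign(nb * nb, -1);
    for (int i = 0; i < n; ++i) {
      int bx = (int)(S.x[i] / bw) % nb, by = (int)(S.y[i] / bw) % nb;
      if (bx < 0) bx += nb; if (by < 0) by += nb;
      int b = by * nb + bx;
      binof[i] = b; nxt[i] = head[b]; head[b] = i;
    }
  }
  auto pair_flows = [&](int i, int j) {
    double dx = pimage(S.x[j] - S.x[i], box), dy = pimage(S.y[j] - S.y[i], box);
    if (dx * dx + dy * dy > cut2) return;
    // eval points of i rel. to centre i: A = 0, B = -Ldip*n_i
    // sources of j rel. to centre j:   drag +F at 0, thrust -F at -Ldip*n_j
    double eAx = 0.0, eAy = 0.0, eBx = -P.Ldip * nx[i], eBy = -P.Ldip * ny[i];
    double sAx = dx, sAy = dy, sBx = dx - P.Ldip * nx[j], sBy = dy - P.Ldip * ny[j];
    double gxx, gxy, gyy;
    bool hasFi = (Fx[i] != 0.0 || Fy[i] != 0.0);
    bool hasFj = (Fx[j] != 0.0 || Fy[j] != 0.0);
    if (!hasFi && !hasFj) return;
    // the 4 point-pair tensors serve both directions (G is even and symmetric)
    struct PP { double rx, ry; int ei; double sgn; };
    // ei: eval point of i (0=A,1=B); sgn: +1 drag, -1 thrust (source of j)
    PP pps[4] = {
      {sAx - eAx, sAy - eAy, 0, +1.0}, {sBx - eAx, sBy - eAy, 0, -1.0},
      {sAx - eBx, sAy - eBy, 1, +1.0}, {sBx - eBx, sBy - eBy, 1, -1.0}};
    for (int k = 0; k < 4; ++k) {
      double rx = pps[k].rx, ry = pps[k].ry;
      if (!P.ker.tensor(rx, ry, gxx, gxy, gyy)) continue;
      double sg = pps[k].sgn;
      if (hasFj) { // flow of j evaluated at i's point (r points i->source, G even)
        double wx = sg * (gxx * Fx[j] + gxy * Fy[j]);
        double wy = sg * (gxy * Fx[j] + gyy * Fy[j]);
        if (pps[k].ei == 0) { wAx[i] += wx; wAy[i] += wy; }
        else { wBx[i] += wx; wBy[i] += wy; }
      }
      if (hasFi) {
        // mirrored geometry: eval point of j <-> source of i swap, same tensor.
        // pps index k maps (eval_i, source_j); for the reverse direction the same
        // separation corresponds to (eval_j = source role, source_i = eval role):
        // eval point of j: A if sgn==+1 (drag at centre) else B; source of i: drag
        // if ei==0 (centre) else thrust.
        double sg2 = (pps[k].ei == 0) ? +1.0 : -1.0;
        double wx = sg2 * (gxx * Fx[i] + gxy * Fy[i]);
        double wy = sg2 * (gxy * Fx[i] + gyy * Fy[i]);
        if (sg > 0) { wAx[j] += wx; wAy[j] += wy; }
        else { wBx[j] += wx; wBy[j] += wy; }
      }
    }
  };
  if (all_pairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) pair_flows(i, j);
  } else {
    for (int i = 0; i < n; ++i) {
      int bx = binof[i] % nb, by = binof[i] / nb;
      for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
        int cx2 = (bx + ox + nb) % nb, cy2 = (by + oy + nb) % nb;
        for (int j = head[cy2 * nb + cx2]; j >= 0; j = nxt[j])
          if (j > i) pair_flows(i, j);
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    F.wmx[i] = 0.5 * (wAx[i] + wBx[i]);
    F.wmy[i] = 0.5 * (wAy[i] + wBy[i]);
    F.wrot[i] = (nx[i] * (wAy[i] - wBy[i]) - ny[i] * (wAx[i] - wBx[i])) / P.Ldip;
  }
}

// Candidate contact pairs (centre distance < L + skin), rebuilt per outer
// step; contact substeps re-evaluate exact segment distances on this list.
struct PairList { std::vector<int> pi, pj; };

static void build_pairs(const SimPar &P, const SimState &S, double skin,
                        PairList &PL) {
  PL.pi.clear(); PL.pj.clear();
  int n = P.n;
  double cut = P.L + skin, cut2 = cut * cut, box = P.box;
  int nb = (int)std::floor(box / cut); if (nb < 1) nb = 1;
  double bw = box / nb;
  auto add_if_close = [&](int i, int j) {
    double dx = pimage(S.x[j] - S.x[i], box), dy = pimage(S.y[j] - S.y[i], box);
    if (dx * dx + dy * dy < cut2) { PL.pi.push_back(i); PL.pj.push_back(j); }
  };
  if (nb < 4) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) add_if_close(i, j);
    return;
  }
  std::vector<int> head(nb * nb, -1), nxt(n), binof(n);
  for (int i = 0; i < n; ++i) {
    int bx = (int)(S.x[i] / bw) % nb, by = (int)(S.y[i] / bw) % nb;
    if (bx < 0) bx += nb; if (by < 0) by += nb;
    int b = by * nb + bx;
    binof[i] = b; nxt[i] = head[b]; head[b] = i;
  }
  for (int i = 0; i < n; ++i) {
    int bx = binof[i] % nb, by = binof[i] / nb;
    for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
      int cx2 = (bx + ox + nb) % nb, cy2 = (by + oy + nb) % nb;
      for (int j = head[cy2 * nb + cx2]; j >= 0; j = nxt[j])
        if (j > i) add_if_close(i, j);
    }
  }
}

// Hertzian + tangential-friction contact forces over the candidate list.
// Returns the number of active contacts.
static int contact_forces(const SimPar &P, const SimState &S,
                          const PairList &PL, double *fx, double *fy,
                          double *tq) {
  int n = P.n, nc = 0;
  std::fill(fx, fx + n, 0.0);
  std::fill(fy, fy + n, 0.0);
  std::fill(tq, tq + n, 0.0);
  double a = 0.5 * (P.L - P.e);
  for (size_t k = 0; k < PL.pi.size(); ++k) {
    int i = PL.pi[k], j = PL.pj[k];
    double dx = pimage(S.x[j] - S.x[i], P.box), dy = pimage(S.y[j] - S.y[i], P.box);
    double n1x = std::cos(S.th[i]), n1y = std::sin(S.th[i]);
    double n2x = std::cos(S.th[j]), n2y = std::sin(S.th[j]);
    double s, t;
    double d2 = seg_seg(dx, dy, n1x, n1y, a, n2x, n2y, a, s, t);
    double d = std::sqrt(d2);
    if (d >= P.e) continue;
    ++nc;
    double ux, uy;
    if (d > 1e-9) {
      ux = (s * n1x - dx - t * n2x) / d;
      uy = (s * n1y - dy - t * n2y) / d;
    } else { ux = -n1y; uy = n1x; }
    double delta = P.e - d;
    double fel = P.Kel * delta * std::sqrt(delta);
    double vx_ = -uy, vy_ = ux;
    double dvt = (S.velx[i] - S.velx[j]) * vx_ + (S.vely[i] - S.vely[j]) * vy_;
    double Fix = fel * ux - P.Kfr * dvt * vx_;
    double Fiy = fel * uy - P.Kfr * dvt * vy_;
    fx[i] += Fix; fy[i] += Fiy;
    fx[j] -= Fix; fy[j] -= Fiy;
    double cx = 0.5 * (s * n1x + dx + t * n2x), cy = 0.5 * (s * n1y + dy + t * n2y);
    tq[i] += cx * Fiy - cy * Fix;
    double cjx = cx - dx, cjy = cy - dy; // contact point rel. centre j
    tq[j] += cjx * (-Fiy) - cjy * (-Fix);
  }
  return nc;
}

// Smooth (propulsion + frozen dipole flows + rotational noise) part of one
// step, recursively halved if any displacement would exceed e/2.
static void smooth_substep(const SimPar &P, SimState &S, const Flows &F,
                           double dt, int depth, long &n_reject) {
  int n = P.n;
  std::vector<double> vx(n), vy(n);
  double max_disp = 0.0;
  for (int i = 0; i < n; ++i) {
    double nxi = std::cos(S.th[i]), nyi = std::sin(S.th[i]);
    double run = (S.motor[i] == 1) ? 1.0 : 0.0;
    vx[i] = run * S.v0[i] * nxi + F.wmx[i];
    vy[i] = run * S.v0[i] * nyi + F.wmy[i];
    double d = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]) * dt;
    if (d > max_disp) max_disp = d;
  }
  if (max_disp > 0.5 * P.e && depth < 8) {
    ++n_reject;
    smooth_substep(P, S, F, 0.5 * dt, depth + 1, n_reject);
    smooth_substep(P, S, F, 0.5 * dt, depth + 1, n_reject);
    return;
  }
  double sdr = std::sqrt(2.0 * P.Dr * dt), sdT = std::sqrt(2.0 * P.DT * dt);
  for (int i = 0; i < n; ++i) {
    S.x[i] += vx[i] * dt; S.y[i] += vy[i] * dt;
    S.ux_unw[i] += vx[i] * dt;
    S.x[i] -= P.box * std::floor(S.x[i] / P.box);
    S.y[i] -= P.box * std::floor(S.y[i] / P.box);
    double dth = F.wrot[i] * dt + sdr * norm_rand();
    if (S.motor[i] == 0) dth += sdT * norm_rand();
    S.th[i] += dth;
  }
}

// One outer Euler step: smooth part at dt, then contact relaxation
// subcycled at dt/n_sub (the Hertzian contacts are stiff: their relaxation
// rate K_el delta^{1/2} / gamma exceeds 1/dt at typical overlaps).
static void do_step(const SimPar &P, SimState &S, const Flows &F, double dt,
                    int n_sub, long &n_reject, long &n_clamp,
                    PairList &PL, std::vector<double> &scr) {
  int n = P.n;
  std::vector<double> x0(S.x), y0(S.y), ux0(S.ux_unw);
  smooth_substep(P, S, F, dt, 0, n_reject);
  if (P.steric) {
    build_pairs(P, S, 1.0, PL);
    if (!PL.pi.empty()) {
      double *fx = scr.data(), *fy = fx + n, *tq = fy + n;
      double dti = dt / n_sub;
      double mpar = 1.0 / P.gpar, mperp = 1.0 / P.gperp;
      for (int s = 0; s < n_sub; ++s) {
        if (contact_forces(P, S, PL, fx, fy, tq) == 0) break;
        for (size_t k = 0; k < PL.pi.size(); ++k) {
          for (int which = 0; which < 2; ++which) {
            int i = which ? PL.pj[k] : PL.pi[k];
            if (fx[i] == 0.0 && fy[i] == 0.0 && tq[i] == 0.0) continue;
            double nxi = std::cos(S.th[i]), nyi = std::sin(S.th[i]);
            double fn = fx[i] * nxi + fy[i] * nyi;
            double mvx = mperp * fx[i] + (mpar - mperp) * fn * nxi;
            double mvy = mperp * fy[i] + (mpar - mperp) * fn * nyi;
            double dxi = mvx * dti, dyi = mvy * dti;
            double dm = std::sqrt(dxi * dxi + dyi * dyi);
            if (dm > 0.25 * P.e) { // safety clamp on runaway overlap forces
              double sc = 0.25 * P.e / dm;
              dxi *= sc; dyi *= sc; ++n_clamp;
            }
            S.x[i] += dxi; S.y[i] += dyi; S.ux_unw[i] += dxi;
            S.x[i] -= P.box * std::floor(S.x[i] / P.box);
            S.y[i] -= P.box * std::floor(S.y[i] / P.box);
            S.th[i] += tq[i] / P.grot * dti;
            fx[i] = fy[i] = tq[i] = 0.0; // avoid double application
          }
        }
      }
    }
  }
  double inv_dt = 1.0 / dt;
  for (int i = 0; i < n; ++i) {
    // wrap orientation to (-pi, pi]
    if (S.th[i] > M_PI || S.th[i] <= -M_PI)
      S.th[i] -= TWO_PI * std::floor((S.th[i] + M_PI) / TWO_PI);
    // total velocity over the outer step (used for contact friction and
    // recorded as the instantaneous cell velocity)
    S.velx[i] = (S.ux_unw[i] - ux0[i]) * inv_dt;
    double dyw = S.y[i] - y0[i];
    dyw = pimage(dyw, P.box);
    S.vely[i] = dyw * inv_dt;
    // pathway update at local ligand concentration (unwrapped x)
    double c = P.c_mid + P.grad * (S.ux_unw[i] - P.x0);
    if (c < 0.0) c = 0.0;
    double f = std::log((1.0 + c / P.Koff) / (1.0 + c / P.Kon));
    double a = 1.0 / (1.0 + std::exp(P.Nrec * (P.eps0 - P.eps1 * S.m[i] + f)));
    double lam = P.lambda0 * std::pow(a / P.a_ss, P.Hmot);
    S.m[i] += (P.kR * (1.0 - a) - P.kB * a) * dt;
    if (S.m[i] < 0.0) S.m[i] = 0.0;
    if (S.m[i] > P.m_max) S.m[i] = P.m_max;
    // motor switching: Poisson tumble initiation, fixed tumble duration tau_t
    if (S.motor[i] == 1) {
      if (unif_rand() < lam * dt) { S.motor[i] = 0; S.timer[i] = 0.0; }
    } else {
      S.timer[i] += dt;
      if (S.timer[i] >= P.tau_t) { S.motor[i] = 1; S.timer[i] = 0.0; }
    }
  }
}

// [[Rcpp::export]]
List cpp_run_sim(List cfg, List state0, NumericVector kz, NumericVector kc1,
                 NumericVector kc2) {
  RNGScope rngs;
  SimPar P;
  P.n = as<int>(cfg["n"]);
  P.box = as<double>(cfg["box"]);
  P.L = as<double>(cfg["L"]); P.e = as<double>(cfg["e"]);
  P.Ldip = as<double>(cfg["L_dip"]);
  P.eta = as<double>(cfg["eta"]);
  P.Kel = as<double>(cfg["K_el"]); P.Kfr = as<double>(cfg["K_fr"]);
  P.gpar = as<double>(cfg["gamma_par"]); P.gperp = as<double>(cfg["gamma_perp"]);
  P.grot = as<double>(cfg["gamma_rot"]);
  P.Dr = as<double>(cfg["D_r"]); P.DT = as<double>(cfg["D_T"]);
  P.tau_t = as<double>(cfg["tau_t"]);
  P.hydro = as<bool>(cfg["hydrodynamics_on"]);
  P.steric = as<bool>(cfg["steric_on"]);
  P.gate_dipole = as<bool>(cfg["gate_dipole"]);
  P.hydro_every = as<int>(cfg["hydro_every"]);
  P.Nrec = as<double>(cfg["N_rec"]); P.Koff = as<double>(cfg["K_off"]);
  P.Kon = as<double>(cfg["K_on"]);
  P.eps0 = as<double>(cfg["eps0"]); P.eps1 = as<double>(cfg["eps1"]);
  P.kR = as<double>(cfg["k_R"]); P.kB = as<double>(cfg["k_B"]);
  P.Hmot = as<double>(cfg["H"]); P.lambda0 = as<double>(cfg["lambda0"]);
  P.m_max = as<double>(cfg["m_max"]); P.a_ss = as<double>(cfg["a_ss"]);
  P.c_mid = as<double>(cfg["c_mid"]); P.grad = as<double>(cfg["grad_c"]);
  P.x0 = as<double>(cfg["x0"]);
  P.ker.kappa = as<double>(cfg["kappa"]);
  P.ker.sqrtk = std::sqrt(P.ker.kappa);
  P.ker.pref = 1.0 / (M_PI * P.eta * as<double>(cfg["h"]) * P.ker.kappa);
  P.ker.r_clamp = as<double>(cfg["r_clamp"]);
  P.ker.r_cutoff = as<double>(cfg["r_cutoff"]);
  P.ker.zmin = kz[0]; P.ker.dz = kz[1] - kz[0]; P.ker.zmax = kz[kz.size() - 1];
  P.ker.c1 = kc1.begin(); P.ker.c2 = kc2.begin(); P.ker.nz = kz.size();

  double dt = as<double>(cfg["dt"]);
  int n_steps = as<int>(cfg["n_steps"]);
  int save_every = as<int>(cfg["save_every"]);
  int n_sub = as<int>(cfg["n_contact_sub"]);

  SimState S;
  NumericVector sx = state0["x"], sy = state0["y"], sth = state0["theta"],
      sv = state0["v_i"], sm = state0["m"], stimer = state0["time_in_state"];
  IntegerVector smot = state0["motor"];
  S.x.assign(sx.begin(), sx.end()); S.y.assign(sy.begin(), sy.end());
  S.th.assign(sth.begin(), sth.end()); S.v0.assign(sv.begin(), sv.end());
  S.m.assign(sm.begin(), sm.end());
  S.timer.assign(stimer.begin(), stimer.end());
  S.motor.assign(smot.begin(), smot.end());
  S.ux_unw.assign(S.x.begin(), S.x.end());
  S.velx.assign(P.n, 0.0); S.vely.assign(P.n, 0.0);

  int n_save = n_steps / save_every;
  NumericMatrix X(n_save, P.n), Y(n_save, P.n), UX(n_save, P.n), TH(n_save, P.n),
      VX(n_save, P.n), VY(n_save, P.n), M(n_save, P.n), A(n_save, P.n);
  IntegerMatrix MOT(n_save, P.n);
  NumericVector times(n_save);

  Flows F;
  compute_flows(P, S, F);
  std::vector<double> scr(3 * P.n);
  PairList PL;
  long n_reject = 0, n_clamp = 0;
  int isave = 0;
  for (int step = 0; step < n_steps; ++step) {
    if (P.hydro && step > 0 && step % P.hydro_every == 0) compute_flows(P, S, F);
    do_step(P, S, F, dt, n_sub, n_reject, n_clamp, PL, scr);
    if ((step + 1) % save_every == 0) {
      times[isave] = (step + 1) * dt;
      for (int i = 0; i < P.n; ++i) {
        X(isave, i) = S.x[i]; Y(isave, i) = S.y[i]; UX(isave, i) = S.ux_unw[i];
        TH(isave, i) = S.th[i]; MOT(isave, i) = S.motor[i];
        VX(isave, i) = S.velx[i]; VY(isave, i) = S.vely[i];
        M(isave, i) = S.m[i];
        double c = P.c_mid + P.grad * (S.ux_unw[i] - P.x0);
        if (c < 0.0) c = 0.0;
        double f = std::log((1.0 + c / P.Koff) / (1.0 + c / P.Kon));
        A(isave, i) = 1.0 / (1.0 + std::exp(P.Nrec * (P.eps0 - P.eps1 * S.m[i] + f)));
        if (!R_finite(S.x[i]) || !R_finite(S.th[i]))
          stop("non-finite state encountered at t = %f (rod %d)", times[isave], i + 1);
      }
      ++isave;
    }
  }
  List fin = List::create(_["x"] = wrap(S.x), _["y"] = wrap(S.y),
                          _["unwrapped_x"] = wrap(S.ux_unw), _["theta"] = wrap(S.th),
                          _["v_i"] = wrap(S.v0), _["m"] = wrap(S.m),
                          _["motor"] = wrap(S.motor),
                          _["time_in_state"] = wrap(S.timer),
                          _["velx"] = wrap(S.velx), _["vely"] = wrap(S.vely));
  return List::create(_["times"] = times, _["x"] = X, _["y"] = Y,
                      _["unwrapped_x"] = UX, _["theta"] = TH, _["motor"] = MOT,
                      _["vx"] = VX, _["vy"] = VY, _["methylation"] = M,
                      _["activity"] = A, _["n_reject"] = (double)n_reject,
                      _["n_clamp"] = (double)n_clamp,
                      _["final"] = fin);
}

// Render anisotropic Gaussian spots onto a frame with periodic wrapping.
// Positions in pixel units (0-based continuous coordinates).
// [[Rcpp::export]]
NumericMatrix cpp_stamp_gaussians(int W, int H, NumericVector px, NumericVector py,
                                  NumericVector amp, NumericVector sig_par,
                                  NumericVector sig_perp, NumericVector theta) {
  NumericMatrix img(H, W); // row = y, col = x
  int n = px.size();
  for (int k = 0; k < n; ++k) {
    double sp = sig_par[k], sq = sig_perp[k];
    double smax = std::max(sp, sq);
    int rad = (int)std::ceil(6.0 * smax);
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    int cx = (int)std::floor(px[k]), cy = (int)std::floor(py[k]);
    for (int oy = -rad; oy <= rad; ++oy) {
      int gy = cy + oy;
      double dy = gy - py[k];
      int wy = gy % H; if (wy < 0) wy += H;
      for (int ox = -rad; ox <= rad; ++ox) {
        int gx = cx + ox;
        double dx = gx - px[k];
        int wx = gx % W; if (wx < 0) wx += W;
        double u = dx * ct + dy * st, v = -dx * st + dy * ct;
        img(wy, wx) += amp[k] *
            std::exp(-0.5 * (u * u / (sp * sp) + v * v / (sq * sq)));
      }
    }
  }
  return img;
}

// Direct (gridless) velocity structure factor: Fourier sum of the discrete
// rod velocities over integer modes k with |k| <= kmax, annularly binned.
// Returns the per-bin sum of |v~(q)|^2 and mode counts, accumulated over
// all supplied frames (rows of X, Y, VX, VY).
// [[Rcpp::export]]
List cpp_velocity_spectrum(NumericMatrix X, NumericMatrix Y,
                           NumericMatrix VX, NumericMatrix VY,
                           double box, int kmax) {
  int nT = X.nrow(), n = X.ncol();
  int nbin = kmax;
  std::vector<double> acc(nbin, 0.0);
  std::vector<int> cnt(nbin, 0);
  double dq = TWO_PI / box;
  for (int kx = 0; kx <= kmax; ++kx) {
    int ky0 = (kx == 0) ? 1 : -kmax; // half-plane, excluding the origin
    for (int ky = ky0; ky <= kmax; ++ky) {
      int b = (int)std::lround(std::sqrt((double)(kx * kx + ky * ky)));
      if (b < 1 || b > nbin) continue;
      double qx = kx * dq, qy = ky * dq;
      double s = 0.0;
      for (int t = 0; t < nT; ++t) {
        double rx = 0, ix = 0, ry = 0, iy = 0;
        for (int i = 0; i < n; ++i) {
          double ph = qx * X(t, i) + qy * Y(t, i);
          double cp = std::cos(ph), sp = std::sin(ph);
          rx += VX(t, i) * cp; ix -= VX(t, i) * sp;
          ry += VY(t, i) * cp; iy -= VY(t, i) * sp;
        }
        s += rx * rx + ix * ix + ry * ry + iy * iy;
      }
      acc[b - 1] += s / nT;
      cnt[b - 1] += 1; // conjugate pair counted once (factor drops in mean)
    }
  }
  return List::create(_["power"] = wrap(acc), _["count"] = wrap(cnt),
                      _["dq"] = dq);
}
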