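// Numerical kernels: explicit advection-diffusion-reaction stepping on the
// voxel grid, and overdamped mechanical relaxation / flow-phase integration
// of the agent assembly (Hookean contact, EPS adhesive springs, Stokes drag).
//
// Internal units throughout: um, fg, s. Spring constants fg s^-2, drag
// coefficients fg s^-1, forces fg um s^-2.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Solute transport: forward-Euler, flux-form central diffusion + first-order
// upwind advection of an imposed shear flow Ux(z) = gammaDot * z, with a
// Dirichlet feed wall (top or bottom), a no-flux opposite wall, and periodic
// lateral boundaries. Reaction source per voxel:
//   R(S) = sum_q A[vox,q] * S/(K[q]+S) + B[vox].
// Consumption enters with negative A/B. Returns after `nsteps` steps or as
// soon as the per-step relative change falls below tolRel.
// [[Rcpp::export]]
List cpp_diffuse(NumericVector S, NumericVector De, NumericMatrix A,
                 NumericVector K, NumericVector B,
                 int nx, int ny, int nz,
                 double hx, double hy, double hz,
                 double dt, int nsteps, double Sb, int feedMode,
                 double gammaDot, double tolRel, double Sref) {
  // feedMode: 0 = closed (no Dirichlet wall), 1 = top feed, 2 = bottom feed
  int nvox = nx * ny * nz;
  if (S.size() != nvox) stop("field size mismatch");
  std::vector<double> s(S.begin(), S.end());
  std::vector<double> snew(nvox);
  int q = A.ncol();
  double lastChange = NA_REAL;
  int step = 0;
  for (step = 0; step < nsteps; ++step) {
    std::copy(s.begin(), s.end(), snew.begin());
    // x faces (periodic), diffusion + upwind advection (flow is +x for z>0)
    for (int k = 0; k < nz; ++k) {
      double ux = gammaDot * (k + 0.5) * hz;
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int ip = (i + 1) % nx;
          int a = idx3(i, j, k, nx, ny), b = idx3(ip, j, k, nx, ny);
          double dface = 0.5 * (De[a] + De[b]);
          double flux = -dface * (s[b] - s[a]) / hx;     // diffusive, +x
          if (ux != 0.0) flux += ux * (ux > 0 ? s[a] : s[b]);
          double d = dt * flux / hx;
          snew[a] -= d;
          snew[b] += d;
        }
      }
    }
    // y faces (periodic), diffusion only
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        int jp = (j + 1) % ny;
        for (int i = 0; i < nx; ++i) {
          int a = idx3(i, j, k, nx, ny), b = idx3(i, jp, k, nx, ny);
          double dface = 0.5 * (De[a] + De[b]);
          double flux = -dface * (s[b] - s[a]) / hy;
          double d = dt * flux / hy;
          snew[a] -= d;
          snew[b] += d;
        }
      }
    // z interior faces
    for (int k = 0; k + 1 < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = idx3(i, j, k, nx, ny), b = idx3(i, j, k + 1, nx, ny);
          double dface = 0.5 * (De[a] + De[b]);
          double flux = -dface * (s[b] - s[a]) / hz;
          double d = dt * flux / hz;
          snew[a] -= d;
          snew[b] += d;
        }
    // z boundary: Dirichlet S = Sb at the feed wall (half-cell distance),
    // no-flux at the opposite wall (nothing to do).
    if (feedMode != 0)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = (feedMode == 1) ? idx3(i, j, nz - 1, nx, ny)
                                  : idx3(i, j, 0, nx, ny);
          snew[a] += dt * De[a] * 2.0 * (Sb - s[a]) / (hz * hz);
        }
    // reaction: production explicit, destruction semi-implicit (Patankar),
    // so stiff Monod sinks stay positive and stable at the transport dt and
    // converge to the exact steady state
    if (q > 0 || B.size() == (R_xlen_t)nvox) {
      for (int v = 0; v < nvox; ++v) {
        double prod = 0.0, dest = 0.0; // dest = destruction rate per unit S
        double b = B[v];
        if (b >= 0.0) prod += b;
        else dest += -b / std::max(s[v], 1e-300);
        for (int c = 0; c < q; ++c) {
          double a = A(v, c);
          if (a > 0.0) prod += a * s[v] / (K[c] + s[v]);
          else if (a < 0.0) dest += -a / (K[c] + s[v]);
        }
        if (prod != 0.0 || dest != 0.0)
          snew[v] = (snew[v] + dt * prod) / (1.0 + dt * dest);
      }
    }
    double change = 0.0;
    for (int v = 0; v < nvox; ++v) {
      if (snew[v] < 0.0) snew[v] = 0.0;
      double d = std::fabs(snew[v] - s[v]);
      if (d > change) change = d;
      if (!std::isfinite(snew[v])) stop("solute solver produced NaN/Inf");
    }
    s.swap(snew);
    lastChange = change / Sref;
    if (lastChange < tolRel) { ++step; break; }
  }
  NumericVector out(s.begin(), s.end());
  out.attr("dim") = S.attr("dim");
  return List::create(_["S"] = out, _["steps"] = step,
                      _["relChange"] = lastChange);
}

// ---------------------------------------------------------------------------
// Mechanics helpers

struct Box {
  double Lx, Ly, Lz;
  bool perX, perY;
  inline void minImage(double &dx, double &dy) const {
    if (perX) { if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx; }
    if (perY) { if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly; }
  }
  inline void wrap(double &x, double &y) const {
    if (perX) { x = std::fmod(x, Lx); if (x < 0) x += Lx; }
    if (perY) { y = std::fmod(y, Ly); if (y < 0) y += Ly; }
  }
};

// cell-list pair enumeration; calls f(i, j, dx, dy, dz, dist) for every pair
// with dist < cutRadFac*(r_i + r_j), each pair exactly once
template <typename F>
static void forPairs(const std::vector<double> &x, const std::vector<double> &y,
                     const std::vector<double> &z, const std::vector<double> &r,
                     const Box &box, double cutRadFac, F f) {
  int n = (int)x.size();
  if (n < 2) return;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cut = cutRadFac * 2.0 * rmax + 1e-9;
  int ncx = std::max(1, (int)std::floor(box.Lx / cut));
  int ncy = std::max(1, (int)std::floor(box.Ly / cut));
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) { zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]); }
  double zspan = std::max(zmax - zmin, cut);
  int ncz = std::max(1, (int)std::floor(zspan / cut));
  double cx = box.Lx / ncx, cy = box.Ly / ncy, cz = zspan / ncz;

  std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    Box b2 = box; b2.wrap(xi, yi);
    int a = std::min(ncx - 1, std::max(0, (int)std::floor(xi / cx)));
    int b = std::min(ncy - 1, std::max(0, (int)std::floor(yi / cy)));
    int c = std::min(ncz - 1, std::max(0, (int)std::floor((z[i] - zmin) / cz)));
    ci[i] = a; cj[i] = b; ck[i] = c;
    int cell = a + ncx * (b + ncy * c);
    nxt[i] = head[cell];
    head[cell] = i;
  }
  for (int i = 0; i < n; ++i) {
    for (int da = -1; da <= 1; ++da)
      for (int db = -1; db <= 1; ++db)
        for (int dc = -1; dc <= 1; ++dc) {
          int a = ci[i] + da, b = cj[i] + db, c = ck[i] + dc;
          if (box.perX) a = (a + ncx) % ncx; else if (a < 0 || a >= ncx) continue;
          if (box.perY) b = (b + ncy) % ncy; else if (b < 0 || b >= ncy) continue;
          if (c < 0 || c >= ncz) continue;
          if (ncx <= 2 && da == 1 && box.perX && ncx == 2) { /* allow */ }
          int cell = a + ncx * (b + ncy * c);
          for (int j = head[cell]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
            box.minImage(dx, dy);
            double cc = cutRadFac * (r[i] + r[j]);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < cc * cc) {
              double dist = std::sqrt(d2);
              f(i, j, dx, dy, dz, dist);
            }
          }
        }
  }
}

// when the box has very few cells in a periodic direction the 27-stencil
// may report a pair twice; fall back to O(n^2) for small n or few cells
template <typename F>
static void forPairsSafe(const std::vector<double> &x, const std::vector<double> &y,
                         const std::vector<double> &z, const std::vector<double> &r,
                         const Box &box, double cutRadFac, F f) {
  int n = (int)x.size();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cut = cutRadFac * 2.0 * rmax + 1e-9;
  bool fewCells = (box.perX && box.Lx < 3.0 * cut) ||
                  (box.perY && box.Ly < 3.0 * cut);
  if (n <= 64 || fewCells) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        box.minImage(dx, dy);
        double cc = cutRadFac * (r[i] + r[j]);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < cc * cc) f(i, j, dx, dy, dz, std::sqrt(d2));
      }
  } else {
    forPairs(x, y, z, r, box, cutRadFac, f);
  }
}

// Verlet candidate-pair list: pairs within (r_i + r_j + skin), reused across
// iterations until accumulated displacements could invalidate it.
struct PairList {
  std::vector<int> pi, pj;
  double skin;
  std::vector<double> acc;   // per-agent displacement since last build
  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const std::vector<double> &r,
             const Box &box) {
    pi.clear(); pj.clear();
    int n = (int)x.size();
    std::vector<double> rs(n);
    for (int i = 0; i < n; ++i) rs[i] = r[i] + 0.5 * skin;
    forPairsSafe(x, y, z, rs, box, 1.0,
      [&](int i, int j, double, double, double, double) {
        pi.push_back(i); pj.push_back(j);
      });
    acc.assign(n, 0.0);
  }
  bool stale() const {
    double m1 = 0.0, m2 = 0.0;
    for (double a : acc) { if (a > m1) { m2 = m1; m1 = a; } else if (a > m2) m2 = a; }
    return m1 + m2 > skin;
  }
};

struct MechState {
  std::vector<double> x, y, z, r, zeta;
  std::vector<int> li, lj;            // adhesive link endpoints (0-based)
  std::vector<double> lk, ld0;        // spring constant (fg/s^2), rest length
  std::vector<int> lact;
  std::vector<double> wk, wd0;        // wall adhesion per agent (0 = none)
  std::vector<int> wact;
  double kn;
  bool hertz;
  Box box;
};

// elastic forces: Hookean/Hertzian contact + wall contact + adhesive springs
// (with permanent breakage at 2*d0). Returns virial sum(F_ij . d_ij) over
// pairs, and per-agent spring-stiffness totals for time-step control.
static void elasticForces(MechState &st, const PairList &pl, bool contacts,
                          bool adhesion,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<double> &fz, std::vector<double> &keff,
                          double &virial, double &maxOverlap, int &nContact) {
  int n = (int)st.x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  std::fill(keff.begin(), keff.end(), 0.0);
  virial = 0.0; maxOverlap = 0.0; nContact = 0;
  if (contacts) {
    for (size_t c = 0; c < pl.pi.size(); ++c) {
      int i = pl.pi[c], j = pl.pj[c];
      double dx = st.x[j] - st.x[i], dy = st.y[j] - st.y[i],
             dz = st.z[j] - st.z[i];
      st.box.minImage(dx, dy);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rsum = st.r[i] + st.r[j];
      if (d2 >= rsum * rsum) continue;
      double dist = std::sqrt(d2);
      double ov = rsum - dist;
      double fac = 1.0;
      if (st.hertz) {
        double di = 2.0 * st.r[i], dj = 2.0 * st.r[j];
        fac = std::sqrt(ov * 0.5 * di * dj / (di + dj));
      }
      double fmag = fac * st.kn * ov;
      double inv = dist > 1e-12 ? 1.0 / dist : 0.0;
      double nxv = dx * inv, nyv = dy * inv, nzv = dz * inv;
      if (dist <= 1e-12) { nxv = 0; nyv = 0; nzv = 1; } // coincident fallback +z
      fx[i] -= fmag * nxv; fy[i] -= fmag * nyv; fz[i] -= fmag * nzv;
      fx[j] += fmag * nxv; fy[j] += fmag * nyv; fz[j] += fmag * nzv;
      virial += fmag * dist;
      keff[i] += fac * st.kn; keff[j] += fac * st.kn;
      if (ov > maxOverlap) maxOverlap = ov;
      ++nContact;
    }
    // substratum wall (z = 0), wall as particle of infinite radius
    for (int i = 0; i < n; ++i) {
      double ov = st.r[i] - st.z[i];
      if (ov > 0.0) {
        double fac = st.hertz ? std::sqrt(ov * st.r[i]) : 1.0;
        fz[i] += fac * st.kn * ov;
        keff[i] += fac * st.kn;
        virial += fac * st.kn * ov * st.z[i];
        if (ov > maxOverlap) maxOverlap = ov;
        ++nContact;
      }
    }
  }
  if (adhesion) {
    for (size_t l = 0; l < st.li.size(); ++l) {
      if (!st.lact[l] || st.lk[l] <= 0.0) continue;
      int i = st.li[l], j = st.lj[l];
      double dx = st.x[j] - st.x[i], dy = st.y[j] - st.y[i], dz = st.z[j] - st.z[i];
      st.box.minImage(dx, dy);
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dist >= 2.0 * st.ld0[l]) { st.lact[l] = 0; continue; } // link breaks
      if (dist < 1e-12) continue;
      double fmag = st.lk[l] * (dist - st.ld0[l]); // >0 stretched => attract
      double inv = 1.0 / dist;
      fx[i] += fmag * dx * inv; fy[i] += fmag * dy * inv; fz[i] += fmag * dz * inv;
      fx[j] -= fmag * dx * inv; fy[j] -= fmag * dy * inv; fz[j] -= fmag * dz * inv;
      virial -= fmag * dist;
      keff[i] += st.lk[l]; keff[j] += st.lk[l];
    }
    // adhesive links to the substratum
    for (int i = 0; i < n; ++i) {
      if (!st.wact[i] || st.wk[i] <= 0.0) continue;
      if (st.z[i] >= 2.0 * st.wd0[i]) { st.wact[i] = 0; continue; }
      double fmag = st.wk[i] * (st.z[i] - st.wd0[i]);
      fz[i] -= fmag;
      virial -= fmag * st.z[i];
      keff[i] += st.wk[i];
    }
  }
}

static MechState makeState(NumericMatrix pos, NumericVector r, NumericVector zeta,
                           IntegerMatrix links, NumericVector lk, NumericVector ld0,
                           LogicalVector lact, NumericVector wk, NumericVector wd0,
                           LogicalVector wact, double kn, bool hertz,
                           double Lx, double Ly, double Lz, bool perX, bool perY) {
  MechState st;
  int n = pos.nrow();
  st.x.assign(n, 0); st.y.assign(n, 0); st.z.assign(n, 0);
  for (int i = 0; i < n; ++i) { st.x[i] = pos(i, 0); st.y[i] = pos(i, 1); st.z[i] = pos(i, 2); }
  st.r.assign(r.begin(), r.end());
  st.zeta.assign(zeta.begin(), zeta.end());
  int m = links.nrow();
  st.li.resize(m); st.lj.resize(m);
  for (int l = 0; l < m; ++l) { st.li[l] = links(l, 0) - 1; st.lj[l] = links(l, 1) - 1; }
  st.lk.assign(lk.begin(), lk.end());
  st.ld0.assign(ld0.begin(), ld0.end());
  st.lact.assign(lact.begin(), lact.end());
  st.wk.assign(wk.begin(), wk.end());
  st.wd0.assign(wd0.begin(), wd0.end());
  st.wact.assign(wact.begin(), wact.end());
  st.kn = kn; st.hertz = hertz;
  st.box.Lx = Lx; st.box.Ly = Ly; st.box.Lz = Lz;
  st.box.perX = perX; st.box.perY = perY;
  return st;
}

static List packResult(const MechState &st, const std::vector<double> &vx,
                       const std::vector<double> &vy, const std::vector<double> &vz,
                       const std::vector<double> &ptrace, double pressure,
                       int iters, double simTime) {
  int n = (int)st.x.size();
  NumericMatrix pos(n, 3), vel(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = st.x[i]; pos(i, 1) = st.y[i]; pos(i, 2) = st.z[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
  }
  return List::create(
    _["pos"] = pos, _["vel"] = vel,
    _["linkActive"] = LogicalVector(st.lact.begin(), st.lact.end()),
    _["wallActive"] = LogicalVector(st.wact.begin(), st.wact.end()),
    _["pressure"] = pressure,
    _["pressureTrace"] = NumericVector(ptrace.begin(), ptrace.end()),
    _["iters"] = iters, _["time"] = simTime);
}

// Relaxation to force equilibrium: FIRE minimization (the standard DEM
// statics algorithm) with stiffness-preconditioned inertia m_i = keff_i, so
// every degree of freedom carries a comparable natural frequency regardless
// of how stiff its springs are. Drag loads enter through ext. Stops when the
// virial pressure |P| = |sum F.d| / (3V) drops below pressTolRel times its
// running maximum (or below pressAbs), or when every agent is within posTol
// of its local force balance, or at maxIter.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, NumericVector r, NumericVector zeta,
               IntegerMatrix links, NumericVector lk, NumericVector ld0,
               LogicalVector lact, NumericVector wk, NumericVector wd0,
               LogicalVector wact, NumericMatrix ext,
               double kn, bool hertz,
               double Lx, double Ly, double Lz, bool perX, bool perY,
               double pressTolRel, double pressAbs, int maxIter,
               double dispCap, double dtCap, double velTol, double posTol,
               bool useFire) {
  MechState st = makeState(pos, r, zeta, links, lk, ld0, lact, wk, wd0, wact,
                           kn, hertz, Lx, Ly, Lz, perX, perY);
  int n = pos.nrow();
  std::vector<double> fx(n), fy(n), fz(n), keff(n), vx(n, 0), vy(n, 0), vz(n, 0);
  std::vector<double> ptrace;
  double vol3 = 3.0 * Lx * Ly * Lz;
  double pref = 0.0, pressure = 0.0, simTime = 0.0;
  int iter = 0;
  bool hasExt = ext.nrow() == n;
  // FIRE controls (dimensionless time, unit natural frequency)
  const double dt0 = 0.10, dtMaxF = 0.60, fInc = 1.1, fDec = 0.5,
               alpha0 = 0.25, fAlpha = 0.99;
  double dtF = dt0, alpha = alpha0;
  int nPos = 0;
  PairList pl; pl.skin = 0.3;
  pl.build(st.x, st.y, st.z, st.r, st.box);
  for (iter = 0; iter < maxIter; ++iter) {
    if (pl.stale()) pl.build(st.x, st.y, st.z, st.r, st.box);
    double virial, maxOv; int nc;
    elasticForces(st, pl, true, true, fx, fy, fz, keff, virial, maxOv, nc);
    pressure = std::fabs(virial) / vol3;
    ptrace.push_back(pressure);
    if (pressure > pref) pref = pressure;
    bool atEq = true;
    double power = 0.0, vnorm2 = 0.0, fnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (hasExt) { fx[i] += ext(i, 0); fy[i] += ext(i, 1); fz[i] += ext(i, 2); }
      double fmag2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (!std::isfinite(fmag2)) stop("mechanical relaxation diverged");
      if (atEq) {
        if (keff[i] > 0.0) {
          if (std::sqrt(fmag2) / keff[i] > posTol) atEq = false;
        } else if (std::sqrt(fmag2) / st.zeta[i] > velTol) atEq = false;
      }
    }
    bool conv = (pressure <= std::max(pressTolRel * pref, 0.0) + pressAbs) ||
                (pref <= pressAbs) || atEq;
    if (conv && iter > 0) break;
    if (!useFire) {
      // overdamped per-agent descent: v = F/zeta, step bounded by the
      // agent's own stiffness — exact inertia-free trajectories, monotone
      // approach (no overshoot); used for small systems
      for (int i = 0; i < n; ++i) {
        vx[i] = fx[i] / st.zeta[i]; vy[i] = fy[i] / st.zeta[i];
        vz[i] = fz[i] / st.zeta[i];
        double dt = dtCap;
        if (keff[i] > 0.0) dt = std::min(dt, 0.4 * st.zeta[i] / keff[i]);
        double vv = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        if (vv > 0.0) dt = std::min(dt, dispCap / vv);
        st.x[i] += vx[i] * dt; st.y[i] += vy[i] * dt; st.z[i] += vz[i] * dt;
        st.box.wrap(st.x[i], st.y[i]);
        pl.acc[i] += vv * dt;
      }
      simTime += dtF;
      continue;
    }
    // preconditioned accelerations a_i = F_i / keff_i (units: um per unit
    // dimensionless time^2); agents without springs coast overdamped
    for (int i = 0; i < n; ++i) {
      double m = keff[i] > 0.0 ? keff[i] : st.zeta[i];
      double ax = fx[i] / m, ay = fy[i] / m, az = fz[i] / m;
      vx[i] += dtF * ax; vy[i] += dtF * ay; vz[i] += dtF * az;
      power += fx[i] * vx[i] + fy[i] * vy[i] + fz[i] * vz[i];
      vnorm2 += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      fnorm2 += (fx[i] / m) * (fx[i] / m) + (fy[i] / m) * (fy[i] / m) +
                (fz[i] / m) * (fz[i] / m);
    }
    if (power > 0.0) {
      double mix = alpha * std::sqrt(vnorm2 / std::max(fnorm2, 1e-300));
      for (int i = 0; i < n; ++i) {
        double m = keff[i] > 0.0 ? keff[i] : st.zeta[i];
        vx[i] = (1.0 - alpha) * vx[i] + mix * fx[i] / m;
        vy[i] = (1.0 - alpha) * vy[i] + mix * fy[i] / m;
        vz[i] = (1.0 - alpha) * vz[i] + mix * fz[i] / m;
      }
      if (++nPos > 5) { dtF = std::min(dtF * fInc, dtMaxF); alpha *= fAlpha; }
    } else {
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      std::fill(vz.begin(), vz.end(), 0.0);
      dtF = std::max(dtF * fDec, 1e-4);
      alpha = alpha0;
      nPos = 0;
    }
    for (int i = 0; i < n; ++i) {
      double dxs = vx[i] * dtF, dys = vy[i] * dtF, dzs = vz[i] * dtF;
      double dd = std::sqrt(dxs * dxs + dys * dys + dzs * dzs);
      if (dd > dispCap) { double s = dispCap / dd; dxs *= s; dys *= s; dzs *= s; }
      st.x[i] += dxs; st.y[i] += dys; st.z[i] += dzs;
      st.box.wrap(st.x[i], st.y[i]);
      pl.acc[i] += dd < dispCap ? dd : dispCap;
    }
    simTime += dtF;
  }
  // report overdamped terminal velocities for the converged configuration
  for (int i = 0; i < n; ++i) {
    vx[i] = fx[i] / st.zeta[i]; vy[i] = fy[i] / st.zeta[i]; vz[i] = fz[i] / st.zeta[i];
  }
  return packResult(st, vx, vy, vz, ptrace, pressure, iter, simTime);
}

// Real-time overdamped flow phase: v = U + F_adh/zeta with U = (gammaDot*z,0,0);
// the stiff contacts are handled by positional projection after each step
// (short inner descent on contact forces only). Integrates until Tflow.
// [[Rcpp::export]]
List cpp_flow_phase(NumericMatrix pos, NumericVector r, NumericVector zeta,
                    IntegerMatrix links, NumericVector lk, NumericVector ld0,
                    LogicalVector lact, NumericVector wk, NumericVector wd0,
                    LogicalVector wact,
                    double kn, bool hertz,
                    double Lx, double Ly, double Lz, bool perX, bool perY,
                    double gammaDot, double Tflow, double dtMax,
                    double dispCap, int projIters, double projTolFrac,
                    int maxIter) {
  MechState st = makeState(pos, r, zeta, links, lk, ld0, lact, wk, wd0, wact,
                           kn, hertz, Lx, Ly, Lz, perX, perY);
  int n = pos.nrow();
  std::vector<double> fx(n), fy(n), fz(n), keff(n), vx(n, 0), vy(n, 0), vz(n, 0);
  std::vector<double> ptrace;
  double vol3 = 3.0 * Lx * Ly * Lz;
  double t = 0.0, pressure = 0.0;
  double rmin = 1e300;
  for (int i = 0; i < n; ++i) rmin = std::min(rmin, (double)r[i]);
  int iter = 0;
  PairList pl; pl.skin = 0.4;
  pl.build(st.x, st.y, st.z, st.r, st.box);
  while (t < Tflow && iter < maxIter) {
    ++iter;
    if (pl.stale()) pl.build(st.x, st.y, st.z, st.r, st.box);
    double virial, maxOv; int nc;
    // adhesion + drag advection step
    elasticForces(st, pl, false, true, fx, fy, fz, keff, virial, maxOv, nc);
    double vmax = 0.0, dtStab = 1e300;
    for (int i = 0; i < n; ++i) {
      double U = gammaDot * st.z[i];
      vx[i] = U + fx[i] / st.zeta[i];
      vy[i] = fy[i] / st.zeta[i];
      vz[i] = fz[i] / st.zeta[i];
      double vv = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      if (vv > vmax) vmax = vv;
      if (keff[i] > 0.0) dtStab = std::min(dtStab, 0.25 * st.zeta[i] / keff[i]);
      if (!std::isfinite(vv)) stop("flow phase diverged (NaN velocity)");
    }
    double dt = std::min(dtMax, Tflow - t);
    dt = std::min(dt, dtStab);
    if (vmax > 0.0) dt = std::min(dt, dispCap / vmax);
    for (int i = 0; i < n; ++i) {
      st.x[i] += vx[i] * dt; st.y[i] += vy[i] * dt; st.z[i] += vz[i] * dt;
      st.box.wrap(st.x[i], st.y[i]);
      if (st.z[i] < 0.0) st.z[i] = 0.0;
      pl.acc[i] += std::sqrt(vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]) * dt;
    }
    t += dt;
    // contact projection
    for (int p = 0; p < projIters; ++p) {
      if (pl.stale()) pl.build(st.x, st.y, st.z, st.r, st.box);
      elasticForces(st, pl, true, false, fx, fy, fz, keff, virial, maxOv, nc);
      pressure = std::fabs(virial) / vol3;
      if (maxOv < projTolFrac * rmin) break;
      double vmax2 = 0.0;
      for (int i = 0; i < n; ++i) {
        vx[i] = fx[i] / st.zeta[i]; vy[i] = fy[i] / st.zeta[i]; vz[i] = fz[i] / st.zeta[i];
        double vv = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        if (vv > vmax2) vmax2 = vv;
      }
      if (vmax2 <= 0.0) break;
      for (int i = 0; i < n; ++i) {
        double dtc = dtMax;
        if (keff[i] > 0.0) dtc = std::min(dtc, 0.4 * st.zeta[i] / keff[i]);
        double vv = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        if (vv > 0.0) dtc = std::min(dtc, 0.5 * dispCap / vv);
        st.x[i] += vx[i] * dtc; st.y[i] += vy[i] * dtc; st.z[i] += vz[i] * dtc;
        st.box.wrap(st.x[i], st.y[i]);
        if (st.z[i] < 0.0) st.z[i] = 0.0;
        pl.acc[i] += vv * dtc;
      }
    }
    ptrace.push_back(pressure);
  }
  return packResult(st, vx, vy, vz, ptrace, pressure, iter, t);
}

// total elastic force on each agent (contact + wall + adhesion) plus the
// virial pressure; diagnostic/verification entry point
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector r, NumericVector zeta,
                IntegerMatrix links, NumericVector lk, NumericVector ld0,
                LogicalVector lact, NumericVector wk, NumericVector wd0,
                LogicalVector wact, double kn, bool hertz,
                double Lx, double Ly, double Lz, bool perX, bool perY,
                bool contacts, bool adhesion) {
  MechState st = makeState(pos, r, zeta, links, lk, ld0, lact, wk, wd0, wact,
                           kn, hertz, Lx, Ly, Lz, perX, perY);
  int n = pos.nrow();
  std::vector<double> fx(n), fy(n), fz(n), keff(n);
  PairList pl; pl.skin = 0.0;
  pl.build(st.x, st.y, st.z, st.r, st.box);
  double virial, maxOv; int nc;
  elasticForces(st, pl, contacts, adhesion, fx, fy, fz, keff, virial, maxOv, nc);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["F"] = F,
                      _["pressure"] = std::fabs(virial) / (3.0 * Lx * Ly * Lz),
                      _["virial"] = virial,
                      _["maxOverlap"] = maxOv, _["nContact"] = nc,
                      _["linkActive"] = LogicalVector(st.lact.begin(), st.lact.end()));
}

// all pairs with separation below cutRadFac*(r_i+r_j) (minimum image);
// 1-based indices, plus the distances
// [[Rcpp::export]]
List cpp_close_pairs(NumericMatrix pos, NumericVector r, double cutRadFac,
                     double Lx, double Ly, bool perX, bool perY) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  std::vector<double> rr(r.begin(), r.end());
  Box box; box.Lx = Lx; box.Ly = Ly; box.Lz = 0; box.perX = perX; box.perY = perY;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  forPairsSafe(x, y, z, rr, box, cutRadFac,
    [&](int i, int j, double, double, double, double dist) {
      ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(dist);
    });
  return List::create(_["i"] = IntegerVector(ii.begin(), ii.end()),
                      _["j"] = IntegerVector(jj.begin(), jj.end()),
                      _["dist"] = NumericVector(dd.begin(), dd.end()));
}
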