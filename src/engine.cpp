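// Core numerics: truncated Lennard-Jones + harmonic bonds, velocity-Verlet
// integration with a Nose-Hoover chain thermostat, neighbor lists, and
// contact-graph cluster geometry under cubic periodic boundaries.
// Reduced units throughout: epsilon = sigma = m = k_B = 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  return d - box * std::round(d / box);
}

// branch-only variant: valid when |d| < box (wrapped coordinates), which
// holds for all internal pair differences; avoids a division per component
static inline double min_image_w(double d, double box, double hbox) {
  if (d > hbox) return d - box;
  if (d < -hbox) return d + box;
  return d;
}

static inline double wrap0(double x, double box) {
  // wrap into [0, box); guard the w == box case after rounding
  double w = x - box * std::floor(x / box);
  if (w < 0) w += box;
  if (w >= box) w -= box;
  return w;
}

// ---------------------------------------------------------------------------
// Pair-list construction: cell grid when the box admits >= 3 cells per axis
// at the requested cutoff, otherwise an all-pairs sweep.  Pairs are returned
// with i < j; `excl` holds up to two bonded partners per particle (linear
// chains), marked -1 when absent.
// ---------------------------------------------------------------------------
static void build_pairs(const std::vector<double>& x,
                        const std::vector<double>& y,
                        const std::vector<double>& z,
                        double box, double cutoff,
                        const std::vector<int>& excl,
                        std::vector<int>& pi, std::vector<int>& pj) {
  const int n = (int)x.size();
  pi.clear(); pj.clear();
  const double c2 = cutoff * cutoff;
  const double hbox = box / 2.0;
  bool any_excl = false;
  for (size_t k = 0; k < excl.size(); ++k) if (excl[k] >= 0) { any_excl = true; break; }
  auto excluded = [&](int a, int b) {
    return excl[2 * a] == b || excl[2 * a + 1] == b;
  };
  int nc = (int)std::floor(box / cutoff);
  if (nc >= 3) {
    const double cell = box / nc;
    const int ncells = nc * nc * nc;
    std::vector<int> head(ncells, -1), nxt(n, -1), cx(n), cy(n), cz(n);
    for (int a = 0; a < n; ++a) {
      int ix = (int)(x[a] / cell), iy = (int)(y[a] / cell), iz = (int)(z[a] / cell);
      if (ix >= nc) ix = nc - 1; if (iy >= nc) iy = nc - 1; if (iz >= nc) iz = nc - 1;
      if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
      cx[a] = ix; cy[a] = iy; cz[a] = iz;
      int idx = (ix * nc + iy) * nc + iz;
      nxt[a] = head[idx]; head[idx] = a;
    }
    for (int a = 0; a < n; ++a) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int ix = (cx[a] + dx + nc) % nc;
            int iy = (cy[a] + dy + nc) % nc;
            int iz = (cz[a] + dz + nc) % nc;
            int idx = (ix * nc + iy) * nc + iz;
            for (int b = head[idx]; b != -1; b = nxt[b]) {
              if (b <= a) continue;
              double ddx = min_image_w(x[a] - x[b], box, hbox);
              double ddy = min_image_w(y[a] - y[b], box, hbox);
              double ddz = min_image_w(z[a] - z[b], box, hbox);
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (r2 < c2 && (!any_excl || !excluded(a, b))) { pi.push_back(a); pj.push_back(b); }
            }
          }
    }
  } else {
    for (int a = 0; a < n - 1; ++a)
      for (int b = a + 1; b < n; ++b) {
        double ddx = min_image_w(x[a] - x[b], box, hbox);
        double ddy = min_image_w(y[a] - y[b], box, hbox);
        double ddz = min_image_w(z[a] - z[b], box, hbox);
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 < c2 && (!any_excl || !excluded(a, b))) { pi.push_back(a); pj.push_back(b); }
      }
  }
}

// LJ energy/forces over a verlet pair list (list cutoff >= rcut, so re-check r2)
static double lj_forces(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, double box, double rcut2,
                        const std::vector<int>& pi, const std::vector<int>& pj,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz, double& min_r2, long& n_in) {
  double pe = 0.0;
  n_in = 0;
  const double hbox = box / 2.0;
  const size_t m = pi.size();
  for (size_t k = 0; k < m; ++k) {
    const int a = pi[k], b = pj[k];
    double dx = min_image_w(x[a] - x[b], box, hbox);
    double dy = min_image_w(y[a] - y[b], box, hbox);
    double dz = min_image_w(z[a] - z[b], box, hbox);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rcut2) continue;
    ++n_in;
    if (r2 < min_r2) min_r2 = r2;
    double inv2 = 1.0 / r2;
    double s6 = inv2 * inv2 * inv2;
    double s12 = s6 * s6;
    pe += 4.0 * (s12 - s6);
    double fs = 24.0 * (2.0 * s12 - s6) * inv2;
    fx[a] += fs * dx; fy[a] += fs * dy; fz[a] += fs * dz;
    fx[b] -= fs * dx; fy[b] -= fs * dy; fz[b] -= fs * dz;
  }
  return pe;
}

static double bond_forces(const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& z, double box, double kb,
                          const std::vector<int>& bi, const std::vector<int>& bj,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz) {
  double pe = 0.0;
  for (size_t k = 0; k < bi.size(); ++k) {
    const int a = bi[k], b = bj[k];
    double dx = min_image(x[a] - x[b], box);
    double dy = min_image(y[a] - y[b], box);
    double dz = min_image(z[a] - z[b], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - 1.0;
    pe += kb * dr * dr;
    // F_a = -dU/dr * rhat_ab
    double fs = -2.0 * kb * dr / r;
    fx[a] += fs * dx; fy[a] += fs * dy; fz[a] += fs * dz;
    fx[b] -= fs * dx; fy[b] -= fs * dy; fz[b] -= fs * dz;
  }
  return pe;
}

// [[Rcpp::export]]
List cpp_lj_energy_forces(NumericMatrix pos, double box, double rcut,
                          IntegerMatrix bonds) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int a = 0; a < n; ++a) { x[a] = pos(a, 0); y[a] = pos(a, 1); z[a] = pos(a, 2); }
  std::vector<int> excl(2 * n, -1);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int a = bonds(k, 0) - 1, b = bonds(k, 1) - 1;
    if (excl[2 * a] == -1) excl[2 * a] = b; else excl[2 * a + 1] = b;
    if (excl[2 * b] == -1) excl[2 * b] = a; else excl[2 * b + 1] = a;
  }
  std::vector<int> pi, pj;
  build_pairs(x, y, z, box, rcut, excl, pi, pj);
  double min_r2 = 1e300;
  long n_in = 0;
  double pe = lj_forces(x, y, z, box, rcut * rcut, pi, pj, fx, fy, fz, min_r2, n_in);
  NumericMatrix f(n, 3);
  for (int a = 0; a < n; ++a) { f(a, 0) = fx[a]; f(a, 1) = fy[a]; f(a, 2) = fz[a]; }
  return List::create(_["energy"] = pe, _["forces"] = f,
                      _["min_distance"] = std::sqrt(min_r2));
}

// [[Rcpp::export]]
List cpp_bond_energy_forces(NumericMatrix pos, double box, IntegerMatrix bonds,
                            double kb) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int a = 0; a < n; ++a) { x[a] = pos(a, 0); y[a] = pos(a, 1); z[a] = pos(a, 2); }
  std::vector<int> bi(bonds.nrow()), bj(bonds.nrow());
  for (int k = 0; k < bonds.nrow(); ++k) { bi[k] = bonds(k, 0) - 1; bj[k] = bonds(k, 1) - 1; }
  double pe = bond_forces(x, y, z, box, kb, bi, bj, fx, fy, fz);
  NumericMatrix f(n, 3);
  for (int a = 0; a < n; ++a) { f(a, 0) = fx[a]; f(a, 1) = fy[a]; f(a, 2) = fz[a]; }
  return List::create(_["energy"] = pe, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Nose-Hoover chain (length 3), Martyna-Tuckerman-Klein half-step update.
// Couples to the total kinetic energy; uniform velocity scaling preserves the
// zero total momentum.  Q1 = g kT tdamp^2, Q2 = Q3 = kT tdamp^2.
// ---------------------------------------------------------------------------
struct NHC {
  double vxi1 = 0, vxi2 = 0, vxi3 = 0, xi1 = 0, xi2 = 0, xi3 = 0;
  double Q1, Q2, Q3, gkT, kT;
  void init(double g, double kT_, double tdamp) {
    kT = kT_; gkT = g * kT_;
    Q1 = g * kT_ * tdamp * tdamp;
    Q2 = kT_ * tdamp * tdamp;
    Q3 = Q2;
  }
  // advance the chain by dt2 = dt/2 and return the velocity scale factor
  double half_step(double& K, double dt2) {
    const double dt4 = dt2 / 2.0, dt8 = dt2 / 4.0;
    double G3 = (Q2 * vxi2 * vxi2 - kT) / Q3;
    vxi3 += G3 * dt4;
    double G2 = (Q1 * vxi1 * vxi1 - kT) / Q2;
    vxi2 *= std::exp(-vxi3 * dt8); vxi2 += G2 * dt4; vxi2 *= std::exp(-vxi3 * dt8);
    double G1 = (2.0 * K - gkT) / Q1;
    vxi1 *= std::exp(-vxi2 * dt8); vxi1 += G1 * dt4; vxi1 *= std::exp(-vxi2 * dt8);
    double s = std::exp(-vxi1 * dt2);
    K *= s * s;
    xi1 += vxi1 * dt2; xi2 += vxi2 * dt2; xi3 += vxi3 * dt2;
    G1 = (2.0 * K - gkT) / Q1;
    vxi1 *= std::exp(-vxi2 * dt8); vxi1 += G1 * dt4; vxi1 *= std::exp(-vxi2 * dt8);
    G2 = (Q1 * vxi1 * vxi1 - kT) / Q2;
    vxi2 *= std::exp(-vxi3 * dt8); vxi2 += G2 * dt4; vxi2 *= std::exp(-vxi3 * dt8);
    G3 = (Q2 * vxi2 * vxi2 - kT) / Q3;
    vxi3 += G3 * dt4;
    return s;
  }
};

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, double box,
                IntegerMatrix bonds, double k_bond, double rcut,
                double dt, int n_steps, int stride,
                bool nvt, double T_star, double tdamp,
                NumericVector vxi0,
                bool interactions, double skin, double abort_tol) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  std::vector<double> ax(n, 0.0), ay(n, 0.0), az(n, 0.0); // displacement since last list build
  for (int a = 0; a < n; ++a) {
    x[a] = pos0(a, 0); y[a] = pos0(a, 1); z[a] = pos0(a, 2);
    vx[a] = vel0(a, 0); vy[a] = vel0(a, 1); vz[a] = vel0(a, 2);
  }
  std::vector<int> bi(bonds.nrow()), bj(bonds.nrow());
  std::vector<int> excl(2 * n, -1);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int a = bonds(k, 0) - 1, b = bonds(k, 1) - 1;
    bi[k] = a; bj[k] = b;
    if (excl[2 * a] == -1) excl[2 * a] = b; else excl[2 * a + 1] = b;
    if (excl[2 * b] == -1) excl[2 * b] = a; else excl[2 * b + 1] = a;
  }
  const bool has_bonds = bonds.nrow() > 0;
  const double rcut2 = rcut * rcut;
  const double list_cut = rcut + skin;
  const double half_skin2 = (skin / 2.0) * (skin / 2.0);

  std::vector<int> pi, pj;
  double min_r2_run = 1e300;
  long n_rebuilds = 0;

  // shift term: the truncated-force dynamics conserves KE + sum(phi - phi_rc),
  // while the protocol's reported PE stays plain-truncated
  const double inv6 = 1.0 / (rcut2 * rcut2 * rcut2);
  const double phi_rc = 4.0 * (inv6 * inv6 - inv6);
  long n_in_cur = 0;
  auto forces = [&](double& min_r2) -> double {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double pe = 0.0;
    n_in_cur = 0;
    if (interactions)
      pe += lj_forces(x, y, z, box, rcut2, pi, pj, fx, fy, fz, min_r2, n_in_cur);
    if (has_bonds)
      pe += bond_forces(x, y, z, box, k_bond, bi, bj, fx, fy, fz);
    return pe;
  };
  auto kinetic = [&]() {
    double K = 0.0;
    for (int a = 0; a < n; ++a) K += vx[a] * vx[a] + vy[a] * vy[a] + vz[a] * vz[a];
    return 0.5 * K;
  };

  if (interactions) build_pairs(x, y, z, box, list_cut, excl, pi, pj);
  double pe = forces(min_r2_run);
  double K = kinetic();
  const double E0 = pe + K;
  const double E0s = pe - n_in_cur * phi_rc + K;

  NHC nhc;
  double g = (n > 1) ? 3.0 * (n - 1) : 3.0;
  if (nvt) {
    nhc.init(g, T_star, tdamp);
    nhc.vxi1 = vxi0[0]; nhc.vxi2 = vxi0[1]; nhc.vxi3 = vxi0[2];
  }

  const int nf = n_steps / stride;
  List frames_pos(nf), frames_vel(nf);
  NumericVector times(nf), pe_out(nf), ke_out(nf), pe_shift_out(nf);
  NumericMatrix thermo(nf, 3);
  int fidx = 0;

  for (int step = 1; step <= n_steps; ++step) {
    if (nvt) {
      double s = nhc.half_step(K, dt / 2.0);
      for (int a = 0; a < n; ++a) { vx[a] *= s; vy[a] *= s; vz[a] *= s; }
    }
    for (int a = 0; a < n; ++a) {
      vx[a] += 0.5 * dt * fx[a]; vy[a] += 0.5 * dt * fy[a]; vz[a] += 0.5 * dt * fz[a];
      double dx = dt * vx[a], dy = dt * vy[a], dz = dt * vz[a];
      x[a] = wrap0(x[a] + dx, box); y[a] = wrap0(y[a] + dy, box); z[a] = wrap0(z[a] + dz, box);
      ax[a] += dx; ay[a] += dy; az[a] += dz;
    }
    if (interactions) {
      double dmax2 = 0.0;
      for (int a = 0; a < n; ++a) {
        double d2 = ax[a] * ax[a] + ay[a] * ay[a] + az[a] * az[a];
        if (d2 > dmax2) dmax2 = d2;
      }
      if (dmax2 > half_skin2) {
        build_pairs(x, y, z, box, list_cut, excl, pi, pj);
        std::fill(ax.begin(), ax.end(), 0.0);
        std::fill(ay.begin(), ay.end(), 0.0);
        std::fill(az.begin(), az.end(), 0.0);
        ++n_rebuilds;
      }
    }
    double min_r2 = 1e300;
    pe = forces(min_r2);
    if (min_r2 < min_r2_run) min_r2_run = min_r2;
    for (int a = 0; a < n; ++a) {
      vx[a] += 0.5 * dt * fx[a]; vy[a] += 0.5 * dt * fy[a]; vz[a] += 0.5 * dt * fz[a];
    }
    K = kinetic();
    if (nvt) {
      double s = nhc.half_step(K, dt / 2.0);
      for (int a = 0; a < n; ++a) { vx[a] *= s; vy[a] *= s; vz[a] *= s; }
    } else if (abort_tol > 0) {
      double E = pe - n_in_cur * phi_rc + K;
      double denom = std::max(std::fabs(E0s), 1.0);
      if (std::fabs(E - E0s) / denom > abort_tol)
        stop("NVE energy divergence at step %d: E0 = %.6g, E = %.6g (relative drift %.3g); reduce dt",
             step, E0s, E, std::fabs(E - E0s) / denom);
    }
    if (step % stride == 0) {
      NumericMatrix P(n, 3), V(n, 3);
      for (int a = 0; a < n; ++a) {
        P(a, 0) = x[a]; P(a, 1) = y[a]; P(a, 2) = z[a];
        V(a, 0) = vx[a]; V(a, 1) = vy[a]; V(a, 2) = vz[a];
      }
      frames_pos[fidx] = P; frames_vel[fidx] = V;
      times[fidx] = step * dt; pe_out[fidx] = pe; ke_out[fidx] = K;
      pe_shift_out[fidx] = pe - n_in_cur * phi_rc;
      thermo(fidx, 0) = nhc.vxi1; thermo(fidx, 1) = nhc.vxi2; thermo(fidx, 2) = nhc.vxi3;
      ++fidx;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["times"] = times, _["positions"] = frames_pos, _["velocities"] = frames_vel,
    _["pe"] = pe_out, _["ke"] = ke_out, _["pe_shifted"] = pe_shift_out,
    _["thermostat"] = thermo,
    _["E0"] = E0, _["E0_shifted"] = E0s,
    _["min_distance"] = std::sqrt(min_r2_run),
    _["n_rebuilds"] = (double)n_rebuilds);
}

// ---------------------------------------------------------------------------
// Contact graph and cluster geometry
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, double box, double cutoff) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int a = 0; a < n; ++a) { x[a] = pos(a, 0); y[a] = pos(a, 1); z[a] = pos(a, 2); }
  std::vector<int> excl(2 * n, -1), pi, pj;
  build_pairs(x, y, z, box, cutoff, excl, pi, pj);
  // build_pairs uses strict r < cutoff; the contact rule is r <= cutoff.
  // Build with a hair above and filter exactly.
  pi.clear(); pj.clear();
  build_pairs(x, y, z, box, cutoff * (1.0 + 1e-12) + 1e-12, excl, pi, pj);
  std::vector<int> ki, kj;
  const double c2 = cutoff * cutoff;
  for (size_t k = 0; k < pi.size(); ++k) {
    double dx = min_image(x[pi[k]] - x[pj[k]], box);
    double dy = min_image(y[pi[k]] - y[pj[k]], box);
    double dz = min_image(z[pi[k]] - z[pj[k]], box);
    if (dx * dx + dy * dy + dz * dz <= c2) { ki.push_back(pi[k]); kj.push_back(pj[k]); }
  }
  IntegerMatrix out(ki.size(), 2);
  for (size_t k = 0; k < ki.size(); ++k) { out(k, 0) = ki[k] + 1; out(k, 1) = kj[k] + 1; }
  return out;
}

// Union-find over n nodes given an edge list; labels numbered 1..k in order
// of first appearance by node index.
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerMatrix pairs) {
  std::vector<int> parent(n);
  for (int a = 0; a < n; ++a) parent[a] = a;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int k = 0; k < pairs.nrow(); ++k) {
    int ra = find(pairs(k, 0) - 1), rb = find(pairs(k, 1) - 1);
    if (ra != rb) parent[rb] = ra;
  }
  IntegerVector labels(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int a = 0; a < n; ++a) {
    int r = find(a);
    if (remap[r] == 0) remap[r] = ++next;
    labels[a] = remap[r];
  }
  return labels;
}

// Per-cluster geometry with periodic unwrapping: BFS over the contact graph
// from the lowest-index member, children placed by minimum-image displacement
// from their parent.  Returns size, radius of gyration, max unwrapped extent
// over the three axes, lowest member index, and a reached-all flag per cluster.
// [[Rcpp::export]]
List cpp_cluster_geometry(NumericMatrix pos, double box, IntegerMatrix pairs,
                          IntegerVector labels) {
  const int n = pos.nrow();
  int ncl = 0;
  for (int a = 0; a < n; ++a) if (labels[a] > ncl) ncl = labels[a];
  // CSR adjacency
  std::vector<int> deg(n, 0);
  for (int k = 0; k < pairs.nrow(); ++k) { ++deg[pairs(k, 0) - 1]; ++deg[pairs(k, 1) - 1]; }
  std::vector<int> off(n + 1, 0);
  for (int a = 0; a < n; ++a) off[a + 1] = off[a] + deg[a];
  std::vector<int> adj(off[n]);
  std::vector<int> fill(n, 0);
  for (int k = 0; k < pairs.nrow(); ++k) {
    int a = pairs(k, 0) - 1, b = pairs(k, 1) - 1;
    adj[off[a] + fill[a]++] = b;
    adj[off[b] + fill[b]++] = a;
  }
  std::vector<int> root(ncl, -1), size(ncl, 0);
  for (int a = n - 1; a >= 0; --a) { root[labels[a] - 1] = a; }
  for (int a = 0; a < n; ++a) ++size[labels[a] - 1];

  std::vector<double> ux(n), uy(n), uz(n);
  std::vector<char> seen(n, 0);
  std::vector<int> queue_;
  NumericVector rg(ncl), extent(ncl);
  IntegerVector sizes(ncl), min_index(ncl);
  LogicalVector connected(ncl), spanning(ncl);

  for (int c = 0; c < ncl; ++c) {
    int r = root[c];
    queue_.clear();
    queue_.push_back(r);
    seen[r] = 1;
    ux[r] = pos(r, 0); uy[r] = pos(r, 1); uz[r] = pos(r, 2);
    size_t qh = 0;
    int reached = 0;
    bool winds = false;  // cycle through the boundary => percolating cluster
    while (qh < queue_.size()) {
      int a = queue_[qh++]; ++reached;
      for (int t = off[a]; t < off[a + 1]; ++t) {
        int b = adj[t];
        if (labels[b] != labels[a]) continue;
        double wx = ux[a] + min_image(pos(b, 0) - pos(a, 0), box);
        double wy = uy[a] + min_image(pos(b, 1) - pos(a, 1), box);
        double wz = uz[a] + min_image(pos(b, 2) - pos(a, 2), box);
        if (seen[b]) {
          // a previously unwrapped neighbor seen through a different winding
          if (std::fabs(wx - ux[b]) > box / 2 || std::fabs(wy - uy[b]) > box / 2 ||
              std::fabs(wz - uz[b]) > box / 2) winds = true;
          continue;
        }
        seen[b] = 1;
        ux[b] = wx; uy[b] = wy; uz[b] = wz;
        queue_.push_back(b);
      }
    }
    connected[c] = (reached == size[c]);
    double cx = 0, cy = 0, cz = 0;
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300, zmin = 1e300, zmax = -1e300;
    for (size_t q = 0; q < queue_.size(); ++q) {
      int a = queue_[q];
      cx += ux[a]; cy += uy[a]; cz += uz[a];
      if (ux[a] < xmin) xmin = ux[a]; if (ux[a] > xmax) xmax = ux[a];
      if (uy[a] < ymin) ymin = uy[a]; if (uy[a] > ymax) ymax = uy[a];
      if (uz[a] < zmin) zmin = uz[a]; if (uz[a] > zmax) zmax = uz[a];
    }
    int m = (int)queue_.size();
    cx /= m; cy /= m; cz /= m;
    double s2 = 0;
    for (size_t q = 0; q < queue_.size(); ++q) {
      int a = queue_[q];
      double dx = ux[a] - cx, dy = uy[a] - cy, dz = uz[a] - cz;
      s2 += dx * dx + dy * dy + dz * dz;
    }
    rg[c] = std::sqrt(s2 / m);
    double ext = std::max(xmax - xmin, std::max(ymax - ymin, zmax - zmin));
    extent[c] = ext;
    spanning[c] = (ext >= box) || winds;
    sizes[c] = size[c];
    min_index[c] = root[c] + 1;
  }
  return List::create(_["sizes"] = sizes, _["rg"] = rg, _["extent"] = extent,
                      _["spanning"] = spanning, _["min_index"] = min_index,
                      _["connected"] = connected);
}
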