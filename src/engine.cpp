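// Core simulation engine: multi-substrate finite-volume biotransport
// (first-order operator splitting, LOD implicit diffusion-decay with a
// cached-forward-sweep Thomas solver), center-based cell mechanics on a
// spatial interaction grid, Adams-Bashforth position updates, and the
// multi-rate tumor / tumor-immune loop. The R-facing module functions
// wrap the same internals that the full run loop uses.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: one seeded generator per run; every stochastic draw consumes it in a
// fixed order so identical (config, seed) gives bit-identical output.
// ---------------------------------------------------------------------------
struct RunRNG {
  std::mt19937_64 gen;
  explicit RunRNG(uint64_t seed) : gen(seed ^ 0x9e3779b97f4a7c15ULL) {}
  double unif() { // [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    // Box-Muller; no state kept so draw order stays simple to reason about
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  void unit2(double& x, double& y) {
    double th = 2.0 * M_PI * unif();
    x = std::cos(th); y = std::sin(th);
  }
  void unit3(double& x, double& y, double& z) {
    z = 2.0 * unif() - 1.0;
    double th = 2.0 * M_PI * unif();
    double s = std::sqrt(std::max(0.0, 1.0 - z * z));
    x = s * std::cos(th); y = s * std::sin(th);
  }
};

// ---------------------------------------------------------------------------
// Mesh
// ---------------------------------------------------------------------------
struct MeshC {
  int nx, ny, nz;
  double dx, dy, dz, ox, oy, oz;
  int nvox() const { return nx * ny * nz; }
  double voxvol() const { return dx * dy * dz; }
  double Lx() const { return nx * dx; }
  double Ly() const { return ny * dy; }
  double Lz() const { return nz * dz; }
  bool inside(double x, double y, double z) const {
    return x >= ox && x < ox + Lx() && y >= oy && y < oy + Ly() &&
           z >= oz && z < oz + Lz();
  }
  int vix(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / dx);
    int j = (int)std::floor((y - oy) / dy);
    int k = (int)std::floor((z - oz) / dz);
    i = std::min(std::max(i, 0), nx - 1);
    j = std::min(std::max(j, 0), ny - 1);
    k = std::min(std::max(k, 0), nz - 1);
    return i + nx * (j + ny * k);
  }
  static MeshC fromList(const List& L) {
    MeshC m;
    m.nx = as<int>(L["nx"]); m.ny = as<int>(L["ny"]); m.nz = as<int>(L["nz"]);
    m.dx = as<double>(L["dx"]); m.dy = as<double>(L["dy"]); m.dz = as<double>(L["dz"]);
    NumericVector o = L["origin"];
    m.ox = o[0]; m.oy = o[1]; m.oz = o[2];
    return m;
  }
};

static inline double radius_of(double vol) {
  return std::cbrt(3.0 * vol / (4.0 * M_PI));
}

// ---------------------------------------------------------------------------
// Diffusion-decay: LOD with cached Thomas forward sweeps.
// Decay is apportioned equally across the active axes so each 1-D system
// stays tridiagonal and the axes are treated symmetrically.
// ---------------------------------------------------------------------------
struct AxisCache {
  int n;
  double r; // D * dt / dx^2
  std::vector<double> cp;   // c_i / denom_i   (c_i = -r)
  std::vector<double> dinv; // 1 / denom_i
};

struct DiffCache {
  bool ax[3];
  int n_active;
  double dt;
  int m;
  // index: substrate * 3 + axis (only active axes populated)
  std::vector<AxisCache> ac;
};

static AxisCache build_axis(int n, double r, double lam_dt_axis) {
  AxisCache a;
  a.n = n; a.r = r;
  a.cp.assign(n, 0.0);
  a.dinv.assign(n, 0.0);
  // matrix rows: ends have one neighbor (no-flux zero-gradient closure),
  // interior rows have two
  double b0 = 1.0 + lam_dt_axis + (n > 1 ? r : 0.0);
  double denom = b0;
  a.dinv[0] = 1.0 / denom;
  a.cp[0] = (n > 1) ? (-r / denom) : 0.0;
  for (int i = 1; i < n; ++i) {
    double bi = 1.0 + lam_dt_axis + ((i == n - 1) ? r : 2.0 * r);
    denom = bi - (-r) * a.cp[i - 1];
    a.dinv[i] = 1.0 / denom;
    a.cp[i] = (i < n - 1) ? (-r / denom) : 0.0;
  }
  return a;
}

static DiffCache build_cache(const MeshC& mesh, const std::vector<double>& D,
                             const std::vector<double>& lam, double dt) {
  DiffCache c;
  c.ax[0] = mesh.nx > 1; c.ax[1] = mesh.ny > 1; c.ax[2] = mesh.nz > 1;
  c.n_active = (int)c.ax[0] + (int)c.ax[1] + (int)c.ax[2];
  c.dt = dt;
  c.m = (int)D.size();
  c.ac.resize((size_t)c.m * 3);
  int dims[3] = {mesh.nx, mesh.ny, mesh.nz};
  double hs[3] = {mesh.dx, mesh.dy, mesh.dz};
  for (int s = 0; s < c.m; ++s) {
    for (int axis = 0; axis < 3; ++axis) {
      if (!c.ax[axis]) continue;
      double r = D[s] * dt / (hs[axis] * hs[axis]);
      double ldt = lam[s] * dt / c.n_active;
      c.ac[(size_t)s * 3 + axis] = build_axis(dims[axis], r, ldt);
    }
  }
  return c;
}

// Solve all strips of one axis at once, in place. Layout: element (t, v) at
// f[v + nvec * t] where t runs along the recurrence (the solve axis) and v
// indexes the nvec parallel strips contiguously, so the inner loops
// vectorize and the serial recurrence latency is amortized across strips.
static void solve_planes(const AxisCache& a, double* f, int nvec) {
  int n = a.n;
  double r = a.r;
  double d0 = a.dinv[0];
  for (int v = 0; v < nvec; ++v) f[v] *= d0;
  for (int t = 1; t < n; ++t) {
    double dinv = a.dinv[t];
    double* cur = f + (size_t)nvec * t;
    double* prev = cur - nvec;
    for (int v = 0; v < nvec; ++v) cur[v] = (cur[v] + r * prev[v]) * dinv;
  }
  for (int t = n - 2; t >= 0; --t) {
    double cp = a.cp[t];
    double* cur = f + (size_t)nvec * t;
    double* nxt = cur + nvec;
    for (int v = 0; v < nvec; ++v) cur[v] -= cp * nxt[v];
  }
}

// Pin the domain-boundary voxels of active axes to the Dirichlet value.
static void pin_dirichlet(const MeshC& mesh, const bool ax[3], double* f,
                          double val) {
  int nx = mesh.nx, ny = mesh.ny, nz = mesh.nz;
  if (ax[0]) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        f[0 + nx * (j + ny * k)] = val;
        f[(nx - 1) + nx * (j + ny * k)] = val;
      }
  }
  if (ax[1]) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        f[i + nx * (0 + ny * k)] = val;
        f[i + nx * ((ny - 1) + ny * k)] = val;
      }
  }
  if (ax[2]) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        f[i + nx * (j + ny * 0)] = val;
        f[i + nx * (j + ny * (nz - 1))] = val;
      }
  }
}

// One LOD diffusion-decay step for substrate s (field column pointer f).
// `scratch` holds an nx*ny transpose buffer for the x-axis solve.
static void diffusion_decay_substrate(const MeshC& mesh, const DiffCache& c,
                                      int s, int btype, double bval,
                                      const std::vector<double>& lam, double* f,
                                      std::vector<double>& scratch) {
  int nx = mesh.nx, ny = mesh.ny, nz = mesh.nz;
  if (c.n_active == 0) {
    double fac = 1.0 / (1.0 + lam[s] * c.dt);
    for (int v = 0; v < mesh.nvox(); ++v) f[v] *= fac;
    if (btype == 1) pin_dirichlet(mesh, c.ax, f, bval);
    return;
  }
  if (c.ax[0]) {
    const AxisCache& a = c.ac[(size_t)s * 3 + 0];
    if ((int)scratch.size() < nx * ny) scratch.resize((size_t)nx * ny);
    double* T = scratch.data();
    for (int k = 0; k < nz; ++k) {
      double* slab = f + (size_t)nx * ny * k;
      if (ny == 1) {
        solve_planes(a, slab, 1);
      } else {
        // transpose so the recurrence along x sees ny contiguous strips
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) T[j + (size_t)ny * i] = slab[i + (size_t)nx * j];
        solve_planes(a, T, ny);
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) slab[i + (size_t)nx * j] = T[j + (size_t)ny * i];
      }
    }
    if (btype == 1) pin_dirichlet(mesh, c.ax, f, bval);
  }
  if (c.ax[1]) {
    const AxisCache& a = c.ac[(size_t)s * 3 + 1];
    for (int k = 0; k < nz; ++k)
      solve_planes(a, f + (size_t)nx * ny * k, nx);
    if (btype == 1) pin_dirichlet(mesh, c.ax, f, bval);
  }
  if (c.ax[2]) {
    const AxisCache& a = c.ac[(size_t)s * 3 + 2];
    solve_planes(a, f, nx * ny);
    if (btype == 1) pin_dirichlet(mesh, c.ax, f, bval);
  }
}

// ---------------------------------------------------------------------------
// Mechanics: pairwise adhesion/repulsion via a uniform spatial hash whose bin
// edge is at least the maximum mechanical interaction distance.
// ---------------------------------------------------------------------------
struct HashGrid {
  double h, minx, miny, minz;
  int nbx, nby, nbz;
  std::vector<int> start; // CSR offsets, size nbins+1
  std::vector<int> items; // cell indices
  int bin_of(double x, double y, double z) const {
    int ix = std::min(std::max((int)((x - minx) / h), 0), nbx - 1);
    int iy = std::min(std::max((int)((y - miny) / h), 0), nby - 1);
    int iz = std::min(std::max((int)((z - minz) / h), 0), nbz - 1);
    return ix + nbx * (iy + nby * iz);
  }
};

static void build_hash_grid(int n, const double* X, const double* Y,
                            const double* Z, double h, HashGrid& g,
                            std::vector<int>& bin, std::vector<int>& cur) {
  double minx = 0, maxx = 0, miny = 0, maxy = 0, minz = 0, maxz = 0;
  if (n > 0) {
    minx = maxx = X[0]; miny = maxy = Y[0]; minz = maxz = Z[0];
    for (int i = 1; i < n; ++i) {
      minx = std::min(minx, X[i]); maxx = std::max(maxx, X[i]);
      miny = std::min(miny, Y[i]); maxy = std::max(maxy, Y[i]);
      minz = std::min(minz, Z[i]); maxz = std::max(maxz, Z[i]);
    }
  }
  g.h = std::max(h, 1e-6);
  g.minx = minx; g.miny = miny; g.minz = minz;
  g.nbx = std::max(1, (int)((maxx - minx) / g.h) + 1);
  g.nby = std::max(1, (int)((maxy - miny) / g.h) + 1);
  g.nbz = std::max(1, (int)((maxz - minz) / g.h) + 1);
  int nb = g.nbx * g.nby * g.nbz;
  g.start.assign(nb + 1, 0);
  bin.resize(n);
  for (int i = 0; i < n; ++i) {
    bin[i] = g.bin_of(X[i], Y[i], Z[i]);
    g.start[bin[i] + 1]++;
  }
  for (int b = 0; b < nb; ++b) g.start[b + 1] += g.start[b];
  g.items.assign(n, 0);
  cur.assign(g.start.begin(), g.start.end() - 1);
  for (int i = 0; i < n; ++i) g.items[cur[bin[i]]++] = i;
}

static inline uint64_t pair_key(int i, int j) {
  return ((uint64_t)(uint32_t)i << 32) | (uint32_t)j;
}

// Deterministic pseudo-random direction for coincident centers: derived from
// the pair indices so the push-apart never divides by zero and is repeatable.
static inline void coincident_dir(int i, int j, bool threeD, double& ux,
                                  double& uy, double& uz) {
  uint64_t hsh = (uint64_t)i * 2654435761ULL + (uint64_t)j * 40503ULL + 17ULL;
  hsh ^= hsh >> 33; hsh *= 0xff51afd7ed558ccdULL; hsh ^= hsh >> 33;
  double th = 2.0 * M_PI * ((hsh & 0xffffffULL) / (double)0x1000000ULL);
  if (threeD) {
    double zz = 2.0 * (((hsh >> 24) & 0xffffULL) / (double)0x10000ULL) - 1.0;
    double s = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    ux = s * std::cos(th); uy = s * std::sin(th); uz = zz;
  } else {
    ux = std::cos(th); uy = std::sin(th); uz = 0.0;
  }
}

// Adhesion/repulsion interaction of one ordered pair (i, j).
static inline void pair_interact(int i, int j, const double* X,
                                 const double* Y, const double* Z,
                                 const double* R, double rep, double adh,
                                 double factor, double adh_mult,
                                 const std::unordered_set<uint64_t>& boosted,
                                 bool threeD, double* VX, double* VY,
                                 double* VZ) {
  double ddx = X[j] - X[i], ddy = Y[j] - Y[i], ddz = Z[j] - Z[i];
  double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
  double rsum = R[i] + R[j];
  double dmax = factor * rsum;
  if (d2 >= dmax * dmax) return;
  double ux, uy, uz, d = std::sqrt(d2);
  if (d < 1e-9) {
    coincident_dir(std::min(i, j), std::max(i, j), threeD, ux, uy, uz);
    if (i > j) { ux = -ux; uy = -uy; uz = -uz; }
    d = 0.0;
  } else {
    ux = ddx / d; uy = ddy / d; uz = ddz / d;
  }
  double mag = 0.0;
  if (d < rsum) {
    double t = 1.0 - d / rsum;
    mag -= rep * t * t; // push i away from j
  }
  double a = adh;
  if (!boosted.empty() &&
      boosted.count(pair_key(std::min(i, j), std::max(i, j))))
    a *= adh_mult;
  double t2 = 1.0 - d / dmax;
  mag += a * t2 * t2; // pull i toward j
  VX[i] += mag * ux; VY[i] += mag * uy; VZ[i] += mag * uz;
  VX[j] -= mag * ux; VY[j] -= mag * uy; VZ[j] -= mag * uz;
}

// Adhesion/repulsion velocities (no motility) over a prebuilt interaction
// grid. Each unordered pair is visited exactly once: pairs within a bin,
// then pairs against the 13 lexicographically forward neighbor bins.
// `boosted` holds index pairs (attached immune-target pairs) whose adhesion
// is multiplied by adh_mult.
static void velocities_core(int n, const double* X, const double* Y,
                            const double* Z, const double* R, double rep,
                            double adh, double factor, double adh_mult,
                            const std::unordered_set<uint64_t>& boosted,
                            bool threeD, const HashGrid& g, double* VX,
                            double* VY, double* VZ) {
  for (int i = 0; i < n; ++i) { VX[i] = 0; VY[i] = 0; VZ[i] = 0; }
  if (n < 2) return;
  static const int fwd[13][3] = {
      {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
      {1, 0, 1}, {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  for (int iz = 0; iz < g.nbz; ++iz)
    for (int iy = 0; iy < g.nby; ++iy)
      for (int ix = 0; ix < g.nbx; ++ix) {
        int b = ix + g.nbx * (iy + g.nby * iz);
        int s0 = g.start[b], s1 = g.start[b + 1];
        if (s0 == s1) continue;
        for (int ii = s0; ii < s1; ++ii)
          for (int jj = ii + 1; jj < s1; ++jj)
            pair_interact(g.items[ii], g.items[jj], X, Y, Z, R, rep, adh,
                          factor, adh_mult, boosted, threeD, VX, VY, VZ);
        for (int q = 0; q < 13; ++q) {
          int jx = ix + fwd[q][0], jy = iy + fwd[q][1], jz = iz + fwd[q][2];
          if (jx < 0 || jx >= g.nbx || jy < 0 || jy >= g.nby || jz < 0 ||
              jz >= g.nbz)
            continue;
          int b2 = jx + g.nbx * (jy + g.nby * jz);
          int t0 = g.start[b2], t1 = g.start[b2 + 1];
          if (t0 == t1) continue;
          for (int ii = s0; ii < s1; ++ii)
            for (int jj = t0; jj < t1; ++jj)
              pair_interact(g.items[ii], g.items[jj], X, Y, Z, R, rep, adh,
                            factor, adh_mult, boosted, threeD, VX, VY, VZ);
        }
      }
}

// ---------------------------------------------------------------------------
// Exported module primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_bulk_supply(NumericMatrix field, NumericVector S,
                              NumericVector U, NumericVector rho_star,
                              double dt) {
  int nv = field.nrow(), m = field.ncol();
  NumericMatrix out(clone(field));
  for (int s = 0; s < m; ++s) {
    if (S[s] == 0.0 && U[s] == 0.0) continue;
    double add = dt * S[s] * rho_star[s];
    double dinv = 1.0 / (1.0 + dt * (S[s] + U[s]));
    for (int v = 0; v < nv; ++v) out(v, s) = (out(v, s) + add) * dinv;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_cell_exchange(NumericMatrix field, List mesh,
                                NumericMatrix pos, NumericVector W,
                                NumericMatrix S, NumericMatrix U,
                                NumericMatrix RS, double dt) {
  MeshC msh = MeshC::fromList(mesh);
  int n = pos.nrow(), m = field.ncol();
  NumericMatrix out(clone(field));
  double vv = msh.voxvol();
  for (int i = 0; i < n; ++i) {
    if (!msh.inside(pos(i, 0), pos(i, 1), pos(i, 2)))
      stop("cell position outside the domain");
    int v = msh.vix(pos(i, 0), pos(i, 1), pos(i, 2));
    double scale = W[i] / vv;
    for (int s = 0; s < m; ++s) {
      double Se = scale * S(i, s), Ue = scale * U(i, s);
      if (Se == 0.0 && Ue == 0.0) continue;
      out(v, s) = (out(v, s) + dt * Se * RS(i, s)) / (1.0 + dt * (Se + Ue));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_thomas_cache(List mesh, NumericVector D, NumericVector lambda,
                      double dt) {
  MeshC msh = MeshC::fromList(mesh);
  std::vector<double> Dv(D.begin(), D.end()), Lv(lambda.begin(), lambda.end());
  DiffCache c = build_cache(msh, Dv, Lv, dt);
  List per;
  List out;
  List subs(c.m);
  for (int s = 0; s < c.m; ++s) {
    List axes(3);
    for (int axis = 0; axis < 3; ++axis) {
      if (!c.ax[axis]) { axes[axis] = R_NilValue; continue; }
      const AxisCache& a = c.ac[(size_t)s * 3 + axis];
      axes[axis] = List::create(_["n"] = a.n, _["r"] = a.r,
                                _["cp"] = NumericVector(a.cp.begin(), a.cp.end()),
                                _["dinv"] = NumericVector(a.dinv.begin(), a.dinv.end()));
    }
    subs[s] = axes;
  }
  return List::create(_["n_active"] = c.n_active,
                      _["active"] = LogicalVector::create(c.ax[0], c.ax[1], c.ax[2]),
                      _["dt"] = dt, _["sweeps"] = subs);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffusion_decay(NumericMatrix field, List mesh,
                                  NumericVector D, NumericVector lambda,
                                  IntegerVector btype, NumericVector bval,
                                  double dt) {
  MeshC msh = MeshC::fromList(mesh);
  std::vector<double> Dv(D.begin(), D.end()), Lv(lambda.begin(), lambda.end());
  DiffCache c = build_cache(msh, Dv, Lv, dt);
  NumericMatrix out(clone(field));
  std::vector<double> tmp(std::max(std::max(msh.nx, msh.ny), msh.nz));
  for (int s = 0; s < field.ncol(); ++s) {
    double* f = &out(0, s);
    diffusion_decay_substrate(msh, c, s, btype[s], bval[s], Lv, f, tmp);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_compute_velocities(NumericMatrix pos, NumericVector radius,
                                     double repulsion, double adhesion,
                                     double factor, Nullable<NumericMatrix> motility,
                                     Nullable<IntegerMatrix> boosted_pairs,
                                     double adhesion_mult, bool threeD) {
  int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n), R(n);
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2); R[i] = radius[i];
  }
  std::unordered_set<uint64_t> boosted;
  if (boosted_pairs.isNotNull()) {
    IntegerMatrix bp(boosted_pairs);
    for (int r = 0; r < bp.nrow(); ++r) {
      int a = bp(r, 0), b = bp(r, 1); // 0-based indices
      boosted.insert(pair_key(std::min(a, b), std::max(a, b)));
    }
  }
  std::vector<double> VX(n), VY(n), VZ(n);
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, R[i]);
  HashGrid g;
  std::vector<int> binb, curb;
  if (n > 1)
    build_hash_grid(n, X.data(), Y.data(), Z.data(),
                    2.0 * factor * rmax * (1.0 + 1e-12), g, binb, curb);
  velocities_core(n, X.data(), Y.data(), Z.data(), R.data(), repulsion,
                  adhesion, factor, adhesion_mult, boosted, threeD, g,
                  VX.data(), VY.data(), VZ.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = VX[i]; out(i, 1) = VY[i]; out(i, 2) = VZ[i];
  }
  if (motility.isNotNull()) {
    NumericMatrix mo(motility);
    for (int i = 0; i < n; ++i)
      for (int c2 = 0; c2 < 3; ++c2) out(i, c2) += mo(i, c2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full simulation loop
// ---------------------------------------------------------------------------
enum CellState { LIVE = 0, APOPTOTIC = 1, NECROTIC = 2 };
enum CellKind { TUMOR = 0, IMMUNE = 1 };

struct Population {
  std::vector<int> id, kind, state, attached_to; // attached_to: target id or -1
  std::vector<double> x, y, z, vx, vy, vz, pvx, pvy, pvz;
  std::vector<char> hasprev;
  std::vector<double> vol, deathvol, p;
  std::vector<double> mdx, mdy, mdz; // motility direction (immune)
  int next_id = 0;
  std::unordered_map<int, int> idmap;

  int size() const { return (int)id.size(); }
  void rebuild_idmap() {
    idmap.clear();
    for (int i = 0; i < size(); ++i) idmap[id[i]] = i;
  }
  int add(int kd, double X, double Y, double Z, double V, double P) {
    int cid = next_id++;
    id.push_back(cid); kind.push_back(kd); state.push_back(LIVE);
    attached_to.push_back(-1);
    x.push_back(X); y.push_back(Y); z.push_back(Z);
    vx.push_back(0); vy.push_back(0); vz.push_back(0);
    pvx.push_back(0); pvy.push_back(0); pvz.push_back(0);
    hasprev.push_back(0);
    vol.push_back(V); deathvol.push_back(V); p.push_back(P);
    mdx.push_back(0); mdy.push_back(0); mdz.push_back(0);
    idmap[cid] = (int)id.size() - 1;
    return (int)id.size() - 1;
  }
  void erase_indices(std::vector<int>& idxs) { // idxs ascending
    if (idxs.empty()) return;
    std::vector<char> drop(size(), 0);
    for (int ix : idxs) drop[ix] = 1;
    int w = 0;
    for (int i = 0; i < size(); ++i) {
      if (drop[i]) continue;
      if (w != i) {
        id[w] = id[i]; kind[w] = kind[i]; state[w] = state[i];
        attached_to[w] = attached_to[i];
        x[w] = x[i]; y[w] = y[i]; z[w] = z[i];
        vx[w] = vx[i]; vy[w] = vy[i]; vz[w] = vz[i];
        pvx[w] = pvx[i]; pvy[w] = pvy[i]; pvz[w] = pvz[i];
        hasprev[w] = hasprev[i];
        vol[w] = vol[i]; deathvol[w] = deathvol[i]; p[w] = p[i];
        mdx[w] = mdx[i]; mdy[w] = mdy[i]; mdz[w] = mdz[i];
      }
      ++w;
    }
    int nw = w;
    id.resize(nw); kind.resize(nw); state.resize(nw); attached_to.resize(nw);
    x.resize(nw); y.resize(nw); z.resize(nw);
    vx.resize(nw); vy.resize(nw); vz.resize(nw);
    pvx.resize(nw); pvy.resize(nw); pvz.resize(nw);
    hasprev.resize(nw);
    vol.resize(nw); deathvol.resize(nw); p.resize(nw);
    mdx.resize(nw); mdy.resize(nw); mdz.resize(nw);
    rebuild_idmap();
  }
};

struct TumorParams {
  double cycle_rate, apop_rate, necro_thr, o2_sat, o2_uptake;
  double chem_S, chem_rs, target_vol, relax_rate;
  double apop_hl, necro_hl, removal_frac;
};

struct ImmuneParamsC {
  int n; double intro_time, r_A, T_A, bias, r_i, speed, persistence;
  double place_factor, volume, grad_eps;
};

struct MechParams { double rep, adh, factor, adh_mult; };

static void clamp_pos(const MeshC& m, double& x, double& y, double& z) {
  double eps = 1e-6;
  x = std::min(std::max(x, m.ox + eps), m.ox + m.Lx() - eps);
  y = std::min(std::max(y, m.oy + eps), m.oy + m.Ly() - eps);
  z = std::min(std::max(z, m.oz + eps), m.oz + m.Lz() - eps);
}

static void chem_gradient(const MeshC& m, const double* f, int v, double& gx,
                          double& gy, double& gz) {
  int nx = m.nx, ny = m.ny, nz = m.nz;
  int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
  gx = gy = gz = 0.0;
  if (nx > 1) {
    int il = std::max(i - 1, 0), ir = std::min(i + 1, nx - 1);
    gx = (f[ir + nx * (j + ny * k)] - f[il + nx * (j + ny * k)]) /
         ((ir - il) * m.dx);
  }
  if (ny > 1) {
    int jl = std::max(j - 1, 0), jr = std::min(j + 1, ny - 1);
    gy = (f[i + nx * (jr + ny * k)] - f[i + nx * (jl + ny * k)]) /
         ((jr - jl) * m.dy);
  }
  if (nz > 1) {
    int kl = std::max(k - 1, 0), kr = std::min(k + 1, nz - 1);
    gz = (f[i + nx * (j + ny * kr)] - f[i + nx * (j + ny * kl)]) /
         ((kr - kl) * m.dz);
  }
}

// [[Rcpp::export]]
List cpp_run_simulation(List cfg) {
  MeshC mesh = MeshC::fromList(cfg["mesh"]);
  bool threeD = mesh.nz > 1;

  List sub = cfg["substrates"];
  std::vector<double> D = as<std::vector<double>>(sub["D"]);
  std::vector<double> lam = as<std::vector<double>>(sub["lambda"]);
  std::vector<double> bS = as<std::vector<double>>(sub["bulk_S"]);
  std::vector<double> bU = as<std::vector<double>>(sub["bulk_U"]);
  std::vector<double> rs = as<std::vector<double>>(sub["rho_star"]);
  std::vector<int> btype = as<std::vector<int>>(sub["btype"]);
  std::vector<double> bval = as<std::vector<double>>(sub["bval"]);
  std::vector<double> finit = as<std::vector<double>>(sub["init"]);
  int m = (int)D.size();
  int nvox = mesh.nvox();

  int iox = as<int>(cfg["oxygen"]);    // 0-based or -1
  int ich = as<int>(cfg["chemokine"]); // 0-based or -1

  List tL = cfg["tumor"];
  TumorParams tp;
  tp.cycle_rate = as<double>(tL["cycle_entry_rate_max"]);
  tp.apop_rate = as<double>(tL["apoptosis_rate"]);
  tp.necro_thr = as<double>(tL["necrosis_threshold"]);
  tp.o2_sat = as<double>(tL["oxygen_saturation"]);
  tp.o2_uptake = as<double>(tL["oxygen_uptake"]);
  tp.chem_S = as<double>(tL["chemokine_secretion"]);
  tp.chem_rs = as<double>(tL["chemokine_saturation"]);
  tp.target_vol = as<double>(tL["volume"]);
  tp.relax_rate = as<double>(tL["volume_relax_rate"]);
  tp.apop_hl = as<double>(tL["apoptotic_halflife"]);
  tp.necro_hl = as<double>(tL["necrotic_halflife"]);
  tp.removal_frac = as<double>(tL["removal_fraction"]);

  List mL = cfg["mechanics"];
  MechParams mp;
  mp.rep = as<double>(mL["repulsion"]);
  mp.adh = as<double>(mL["adhesion"]);
  mp.factor = as<double>(mL["max_adhesion_factor"]);
  mp.adh_mult = as<double>(mL["attach_adhesion_mult"]);

  List iL = cfg["immune"];
  ImmuneParamsC ip;
  ip.n = as<int>(iL["n"]);
  ip.intro_time = as<double>(iL["introduction_time"]);
  ip.r_A = as<double>(iL["r_A"]);
  ip.T_A = as<double>(iL["T_A"]);
  ip.bias = as<double>(iL["bias"]);
  ip.r_i = as<double>(iL["kill_rate"]);
  ip.speed = as<double>(iL["speed"]);
  ip.persistence = as<double>(iL["persistence_time"]);
  ip.place_factor = as<double>(iL["placement_factor"]);
  ip.volume = as<double>(iL["volume"]);
  ip.grad_eps = as<double>(iL["gradient_epsilon"]);

  List tmL = cfg["times"];
  double duration = as<double>(tmL["duration"]);
  double dt_diff = as<double>(tmL["dt_diffusion"]);
  double dt_mech = as<double>(tmL["dt_mechanics"]);
  double dt_phen = as<double>(tmL["dt_phenotype"]);
  double save_int = as<double>(tmL["save_interval"]);

  RunRNG rng((uint64_t)as<double>(cfg["seed"]));

  // field, column-major per substrate
  std::vector<std::vector<double>> field(m, std::vector<double>(nvox));
  for (int s = 0; s < m; ++s)
    std::fill(field[s].begin(), field[s].end(), finit[s]);

  DiffCache dcache = build_cache(mesh, D, lam, dt_diff);
  std::vector<double> tmp(std::max(std::max(mesh.nx, mesh.ny), mesh.nz));

  // initial cells
  Population pop;
  List cL = cfg["cells"];
  {
    IntegerVector kd = cL["kind"];
    NumericVector cx = cL["x"], cy = cL["y"], cz = cL["z"], cv = cL["volume"],
                  cp_ = cL["oncoprotein"];
    for (int i = 0; i < kd.size(); ++i) {
      double X = cx[i], Y = cy[i], Z = cz[i];
      clamp_pos(mesh, X, Y, Z);
      pop.add(kd[i], X, Y, Z, cv[i], cp_[i]);
    }
  }
  int n_initial = pop.size();
  long n_div = 0, n_rem = 0;

  long n_mech = (long)std::llround(duration / dt_mech);
  int n_diff = std::max(1, (int)std::llround(dt_mech / dt_diff));
  int phen_every = std::max(1, (int)std::llround(dt_phen / dt_mech));
  long save_every = save_int > 0 ? (long)std::llround(save_int / dt_mech) : 0;
  long intro_step =
      ip.n > 0 ? (long)std::llround(ip.intro_time / dt_mech) : -1;

  bool any_bulk = false;
  for (int s = 0; s < m; ++s)
    if (bS[s] != 0.0 || bU[s] != 0.0) any_bulk = true;

  // outputs
  List snapshots;
  std::vector<double> ts_time;
  std::vector<int> ts_live, ts_apop, ts_necro, ts_imm, ts_att;
  std::vector<long> ts_div, ts_rem;

  auto record_ts = [&](double t) {
    int lv = 0, ap = 0, ne = 0, im = 0, at = 0;
    for (int i = 0; i < pop.size(); ++i) {
      if (pop.kind[i] == IMMUNE) {
        ++im;
        if (pop.attached_to[i] >= 0) ++at;
      } else {
        if (pop.state[i] == LIVE) ++lv;
        else if (pop.state[i] == APOPTOTIC) ++ap;
        else ++ne;
      }
    }
    ts_time.push_back(t); ts_live.push_back(lv); ts_apop.push_back(ap);
    ts_necro.push_back(ne); ts_imm.push_back(im); ts_att.push_back(at);
    ts_div.push_back(n_div); ts_rem.push_back(n_rem);
  };

  auto take_snapshot = [&](double t) {
    int n = pop.size();
    IntegerVector oid(n), okind(n), ostate(n), oatt(n);
    NumericVector ox_(n), oy_(n), oz_(n), ovol(n), orad(n), op(n);
    for (int i = 0; i < n; ++i) {
      oid[i] = pop.id[i]; okind[i] = pop.kind[i]; ostate[i] = pop.state[i];
      oatt[i] = pop.attached_to[i];
      ox_[i] = pop.x[i]; oy_[i] = pop.y[i]; oz_[i] = pop.z[i];
      ovol[i] = pop.vol[i]; orad[i] = radius_of(pop.vol[i]); op[i] = pop.p[i];
    }
    NumericMatrix fm(nvox, m);
    for (int s = 0; s < m; ++s)
      std::copy(field[s].begin(), field[s].end(), fm.begin() + (size_t)s * nvox);
    snapshots.push_back(List::create(
        _["time"] = t, _["id"] = oid, _["kind"] = okind, _["x"] = ox_,
        _["y"] = oy_, _["z"] = oz_, _["volume"] = ovol, _["radius"] = orad,
        _["state"] = ostate, _["oncoprotein"] = op, _["attached_to"] = oatt,
        _["fields"] = fm));
  };

  record_ts(0.0);
  take_snapshot(0.0);

  std::vector<int> divide_list, remove_list;
  std::vector<int> exch_vox;
  std::vector<double> exch_add_ox, exch_dinv_ox, exch_add_ch, exch_dinv_ch;
  std::vector<double> VX, VY, VZ, RAD;
  std::vector<int> contacts, binb, curb;

  for (long step = 0; step < n_mech; ++step) {
    // immune introduction: uniformly on a shell just outside the tumor
    if (step == intro_step) {
      double cxm = 0, cym = 0, czm = 0; int nl = 0;
      for (int i = 0; i < pop.size(); ++i)
        if (pop.kind[i] == TUMOR && pop.state[i] == LIVE) {
          cxm += pop.x[i]; cym += pop.y[i]; czm += pop.z[i]; ++nl;
        }
      if (nl > 0) { cxm /= nl; cym /= nl; czm /= nl; }
      else {
        cxm = mesh.ox + mesh.Lx() / 2; cym = mesh.oy + mesh.Ly() / 2;
        czm = mesh.oz + mesh.Lz() / 2;
      }
      double bR = 0;
      for (int i = 0; i < pop.size(); ++i)
        if (pop.kind[i] == TUMOR && pop.state[i] == LIVE) {
          double dd = std::sqrt((pop.x[i] - cxm) * (pop.x[i] - cxm) +
                                (pop.y[i] - cym) * (pop.y[i] - cym) +
                                (pop.z[i] - czm) * (pop.z[i] - czm));
          bR = std::max(bR, dd + radius_of(pop.vol[i]));
        }
      if (bR <= 0) bR = std::min(mesh.Lx(), mesh.Ly()) / 4;
      double rp = ip.place_factor * bR;
      for (int k2 = 0; k2 < ip.n; ++k2) {
        double ux, uy, uz = 0;
        if (threeD) rng.unit3(ux, uy, uz); else rng.unit2(ux, uy);
        double X = cxm + rp * ux, Y = cym + rp * uy, Z = czm + rp * uz;
        clamp_pos(mesh, X, Y, Z);
        pop.add(IMMUNE, X, Y, Z, ip.volume, 0.0);
      }
    }

    int n = pop.size();

    // ---- 1) microenvironment: bulk sources, cell exchange, diffusion ----
    if (m > 0) {
      // precompute per-cell exchange terms (positions/volumes fixed within
      // the mechanics step)
      exch_vox.clear(); exch_add_ox.clear(); exch_dinv_ox.clear();
      exch_add_ch.clear(); exch_dinv_ch.clear();
      double vv = mesh.voxvol();
      for (int i = 0; i < n; ++i) {
        if (pop.kind[i] != TUMOR || pop.state[i] != LIVE) continue;
        double scale = pop.vol[i] / vv;
        exch_vox.push_back(mesh.vix(pop.x[i], pop.y[i], pop.z[i]));
        if (iox >= 0) {
          double Ue = scale * tp.o2_uptake;
          exch_add_ox.push_back(0.0);
          exch_dinv_ox.push_back(1.0 / (1.0 + dt_diff * Ue));
        }
        if (ich >= 0) {
          double Se = scale * tp.chem_S;
          exch_add_ch.push_back(dt_diff * Se * tp.chem_rs);
          exch_dinv_ch.push_back(1.0 / (1.0 + dt_diff * Se));
        }
      }
      for (int kdif = 0; kdif < n_diff; ++kdif) {
        if (any_bulk) {
          for (int s = 0; s < m; ++s) {
            if (bS[s] == 0.0 && bU[s] == 0.0) continue;
            double add = dt_diff * bS[s] * rs[s];
            double dinv = 1.0 / (1.0 + dt_diff * (bS[s] + bU[s]));
            double* f = field[s].data();
            for (int v = 0; v < nvox; ++v) f[v] = (f[v] + add) * dinv;
          }
        }
        size_t ne = exch_vox.size();
        if (iox >= 0 && ne > 0) {
          double* f = field[iox].data();
          for (size_t e = 0; e < ne; ++e)
            f[exch_vox[e]] *= exch_dinv_ox[e];
        }
        if (ich >= 0 && ne > 0) {
          double* f = field[ich].data();
          for (size_t e = 0; e < ne; ++e)
            f[exch_vox[e]] = (f[exch_vox[e]] + exch_add_ch[e]) * exch_dinv_ch[e];
        }
        for (int s = 0; s < m; ++s)
          diffusion_decay_substrate(mesh, dcache, s, btype[s], bval[s], lam,
                                    field[s].data(), tmp);
      }
    }

    // ---- 2+3) phenotype advance and serial division/removal ----
    bool phen_now = ((step + 1) % phen_every) == 0;
    if (phen_now) {
      divide_list.clear(); remove_list.clear();
      double dtp = dt_phen;
      const double* fox = (iox >= 0) ? field[iox].data() : nullptr;
      for (int i = 0; i < pop.size(); ++i) {
        if (pop.kind[i] != TUMOR) continue;
        if (pop.state[i] == LIVE) {
          // death is evaluated before division
          if (rng.unif() < std::min(1.0, tp.apop_rate * dtp)) {
            pop.state[i] = APOPTOTIC; pop.deathvol[i] = pop.vol[i];
            continue;
          }
          double pO2 = fox ? fox[mesh.vix(pop.x[i], pop.y[i], pop.z[i])]
                           : tp.o2_sat;
          if (pO2 < tp.necro_thr) { // strict inequality at the threshold
            pop.state[i] = NECROTIC; pop.deathvol[i] = pop.vol[i];
            continue;
          }
          pop.vol[i] += (1.0 - std::exp(-tp.relax_rate * dtp)) *
                        (tp.target_vol - pop.vol[i]);
          double ramp = (pO2 - tp.necro_thr) / (tp.o2_sat - tp.necro_thr);
          ramp = std::min(std::max(ramp, 0.0), 1.0);
          double rate = pop.p[i] * tp.cycle_rate * ramp;
          if (rng.unif() < std::min(1.0, rate * dtp)) divide_list.push_back(i);
        } else {
          double hl = (pop.state[i] == APOPTOTIC) ? tp.apop_hl : tp.necro_hl;
          pop.vol[i] *= std::pow(0.5, dtp / hl);
          if (pop.vol[i] < tp.removal_frac * pop.deathvol[i])
            remove_list.push_back(i);
        }
      }
      // serial division processing, ascending cell order
      for (int idx : divide_list) {
        if (pop.state[idx] != LIVE)
          stop("internal consistency error: division of a non-live cell");
        double V = pop.vol[idx], half = V / 2.0;
        double r0 = radius_of(V), off = r0 / 2.0;
        double ux, uy, uz = 0;
        if (threeD) rng.unit3(ux, uy, uz); else rng.unit2(ux, uy);
        double px0 = pop.x[idx], py0 = pop.y[idx], pz0 = pop.z[idx];
        double xa = px0 + off * ux, ya = py0 + off * uy, za = pz0 + off * uz;
        double xb = px0 - off * ux, yb = py0 - off * uy, zb = pz0 - off * uz;
        clamp_pos(mesh, xa, ya, za); clamp_pos(mesh, xb, yb, zb);
        pop.vol[idx] = half; pop.x[idx] = xa; pop.y[idx] = ya; pop.z[idx] = za;
        int child = pop.add(TUMOR, xb, yb, zb, half, pop.p[idx]);
        (void)child;
        ++n_div;
      }
      // removal: dissolve attachments before excision (no dangling ids)
      if (!remove_list.empty()) {
        std::unordered_set<int> dead_ids;
        for (int idx : remove_list) dead_ids.insert(pop.id[idx]);
        for (int i = 0; i < pop.size(); ++i) {
          if (pop.kind[i] == IMMUNE && pop.attached_to[i] >= 0 &&
              dead_ids.count(pop.attached_to[i]))
            pop.attached_to[i] = -1;
        }
        std::sort(remove_list.begin(), remove_list.end());
        n_rem += (long)remove_list.size();
        pop.erase_indices(remove_list);
      }
    }
    n = pop.size();

    // grid shared by the immune contact search and the velocity update
    double rmax = 0;
    RAD.resize(n);
    for (int i = 0; i < n; ++i) {
      RAD[i] = radius_of(pop.vol[i]);
      rmax = std::max(rmax, RAD[i]);
    }
    HashGrid grid;
    bool have_grid = false;
    if (n > 1) {
      build_hash_grid(n, pop.x.data(), pop.y.data(), pop.z.data(),
                      2.0 * mp.factor * rmax * (1.0 + 1e-12), grid, binb,
                      curb);
      have_grid = true;
    }

    // ---- immune interactions: attach / kill / detach, motility redraw ----
    if (ip.n > 0 && step >= intro_step) {
      const double* fch = (ich >= 0) ? field[ich].data() : nullptr;
      for (int i = 0; i < n; ++i) {
        if (pop.kind[i] != IMMUNE) continue;
        if (pop.attached_to[i] >= 0) {
          auto it = pop.idmap.find(pop.attached_to[i]);
          if (it == pop.idmap.end())
            stop("internal consistency error: dangling attachment");
          int tgt = it->second;
          if (pop.state[tgt] == LIVE) {
            if (rng.unif() < std::min(1.0, ip.r_i * pop.p[tgt] * dt_mech)) {
              pop.state[tgt] = APOPTOTIC; pop.deathvol[tgt] = pop.vol[tgt];
              pop.attached_to[i] = -1;
              pop.mdx[i] = pop.mdy[i] = pop.mdz[i] = 0.0; // re-pick direction
            } else if (rng.unif() < std::min(1.0, dt_mech / ip.T_A)) {
              pop.attached_to[i] = -1;
            }
          } else {
            // target already dying: kill attempt is a no-op, detach normally
            if (rng.unif() < std::min(1.0, dt_mech / ip.T_A))
              pop.attached_to[i] = -1;
          }
          continue;
        }
        // unattached: motility direction persistence, then contact/attach
        bool nodir = pop.mdx[i] == 0.0 && pop.mdy[i] == 0.0 && pop.mdz[i] == 0.0;
        if (nodir || rng.unif() < dt_mech / ip.persistence) {
          double gx = 0, gy = 0, gz = 0;
          if (fch)
            chem_gradient(mesh, fch,
                          mesh.vix(pop.x[i], pop.y[i], pop.z[i]), gx, gy, gz);
          double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
          double dxn = 0, dyn = 0, dzn = 0;
          for (int tries = 0; tries < 10; ++tries) {
            double ux, uy, uz = 0;
            if (threeD) rng.unit3(ux, uy, uz); else rng.unit2(ux, uy);
            if (gn < ip.grad_eps) { dxn = ux; dyn = uy; dzn = uz; break; }
            double bx = (1 - ip.bias) * ux + ip.bias * gx / gn;
            double by = (1 - ip.bias) * uy + ip.bias * gy / gn;
            double bz = (1 - ip.bias) * uz + ip.bias * gz / gn;
            double bn = std::sqrt(bx * bx + by * by + bz * bz);
            if (bn >= ip.grad_eps) {
              dxn = bx / bn; dyn = by / bn; dzn = bz / bn;
              break;
            }
          }
          pop.mdx[i] = dxn; pop.mdy[i] = dyn; pop.mdz[i] = dzn;
        }
        // contact test against live tumor cells
        contacts.clear();
        if (have_grid) {
          int b = grid.bin_of(pop.x[i], pop.y[i], pop.z[i]);
          int bx = b % grid.nbx, by = (b / grid.nbx) % grid.nby,
              bz = b / (grid.nbx * grid.nby);
          for (int dz2 = -1; dz2 <= 1; ++dz2) {
            int jz = bz + dz2; if (jz < 0 || jz >= grid.nbz) continue;
            for (int dy2 = -1; dy2 <= 1; ++dy2) {
              int jy = by + dy2; if (jy < 0 || jy >= grid.nby) continue;
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                int jx = bx + dx2; if (jx < 0 || jx >= grid.nbx) continue;
                int b2 = jx + grid.nbx * (jy + grid.nby * jz);
                for (int jj = grid.start[b2]; jj < grid.start[b2 + 1]; ++jj) {
                  int j = grid.items[jj];
                  if (j == i || pop.kind[j] != TUMOR || pop.state[j] != LIVE)
                    continue;
                  double ddx = pop.x[j] - pop.x[i], ddy = pop.y[j] - pop.y[i],
                         ddz = pop.z[j] - pop.z[i];
                  double rr = RAD[i] + RAD[j];
                  if (ddx * ddx + ddy * ddy + ddz * ddz <= rr * rr)
                    contacts.push_back(j);
                }
              }
            }
          }
        }
        if (!contacts.empty() &&
            rng.unif() < std::min(1.0, ip.r_A * dt_mech)) {
          int pick = (int)(rng.unif() * contacts.size());
          if (pick >= (int)contacts.size()) pick = (int)contacts.size() - 1;
          pop.attached_to[i] = pop.id[contacts[pick]];
        }
      }
    }

    // ---- 4) velocities ----
    VX.assign(n, 0.0); VY.assign(n, 0.0); VZ.assign(n, 0.0);
    if (n > 1) {
      std::unordered_set<uint64_t> boosted;
      for (int i = 0; i < n; ++i) {
        if (pop.kind[i] == IMMUNE && pop.attached_to[i] >= 0) {
          auto it = pop.idmap.find(pop.attached_to[i]);
          if (it != pop.idmap.end()) {
            int j = it->second;
            boosted.insert(pair_key(std::min(i, j), std::max(i, j)));
          }
        }
      }
      velocities_core(n, pop.x.data(), pop.y.data(), pop.z.data(), RAD.data(),
                      mp.rep, mp.adh, mp.factor, mp.adh_mult, boosted, threeD,
                      grid, VX.data(), VY.data(), VZ.data());
    }
    for (int i = 0; i < n; ++i) {
      if (pop.kind[i] == IMMUNE && pop.attached_to[i] < 0) {
        VX[i] += ip.speed * pop.mdx[i];
        VY[i] += ip.speed * pop.mdy[i];
        VZ[i] += ip.speed * pop.mdz[i];
      }
    }

    // ---- 5) positions: Adams-Bashforth 2 with forward-Euler bootstrap ----
    for (int i = 0; i < n; ++i) {
      double nxp, nyp, nzp;
      if (pop.hasprev[i]) {
        nxp = pop.x[i] + dt_mech * (1.5 * VX[i] - 0.5 * pop.pvx[i]);
        nyp = pop.y[i] + dt_mech * (1.5 * VY[i] - 0.5 * pop.pvy[i]);
        nzp = pop.z[i] + dt_mech * (1.5 * VZ[i] - 0.5 * pop.pvz[i]);
      } else {
        nxp = pop.x[i] + dt_mech * VX[i];
        nyp = pop.y[i] + dt_mech * VY[i];
        nzp = pop.z[i] + dt_mech * VZ[i];
        pop.hasprev[i] = 1;
      }
      clamp_pos(mesh, nxp, nyp, nzp);
      pop.x[i] = nxp; pop.y[i] = nyp; pop.z[i] = nzp;
      pop.pvx[i] = VX[i]; pop.pvy[i] = VY[i]; pop.pvz[i] = VZ[i];
      pop.vx[i] = VX[i]; pop.vy[i] = VY[i]; pop.vz[i] = VZ[i];
    }

    // ---- 6) time and outputs ----
    double t_now = (step + 1) * dt_mech;
    if (phen_now) record_ts(t_now);
    if (save_every > 0 && ((step + 1) % save_every) == 0) take_snapshot(t_now);
  }

  double t_end = n_mech * dt_mech;
  bool final_saved =
      save_every > 0 && n_mech > 0 && (n_mech % save_every) == 0;
  if (!final_saved && n_mech > 0) take_snapshot(t_end);
  if (n_mech == 0 && snapshots.size() == 0) take_snapshot(0.0);
  if (ts_time.empty() || ts_time.back() != t_end) record_ts(t_end);

  List ts = List::create(
      _["time"] = NumericVector(ts_time.begin(), ts_time.end()),
      _["live_tumor"] = IntegerVector(ts_live.begin(), ts_live.end()),
      _["apoptotic"] = IntegerVector(ts_apop.begin(), ts_apop.end()),
      _["necrotic"] = IntegerVector(ts_necro.begin(), ts_necro.end()),
      _["immune"] = IntegerVector(ts_imm.begin(), ts_imm.end()),
      _["attached"] = IntegerVector(ts_att.begin(), ts_att.end()),
      _["divisions"] = NumericVector(ts_div.begin(), ts_div.end()),
      _["removed"] = NumericVector(ts_rem.begin(), ts_rem.end()));

  return List::create(
      _["snapshots"] = snapshots, _["timeseries"] = ts,
      _["counters"] = List::create(_["initial"] = n_initial,
                                   _["divisions"] = (double)n_div,
                                   _["removed"] = (double)n_rem,
                                   _["final"] = pop.size()));
}
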