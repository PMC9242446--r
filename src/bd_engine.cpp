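// Langevin-dynamics engine for a coarse-grained DNA tether (bead-spring chain
// with WCA excluded volume, FENE bonds, cosine bending) plus the lattice layer
// of ParB diffusion / recruitment that runs on top of it.
//
// Reduced units: sigma = 1 (bead size), epsilon = kBT = 1, m = 1, gamma = 1,
// so the Brownian time tau_B = sigma^2 gamma / kBT = 1 and the integration
// step is dt (default 0.01 tau_B). Default integrator is BAOAB Langevin
// (inertial, stable at dt = 0.01 with FENE k = 30); an overdamped
// Euler-Maruyama variant is available for small-dt diffusion checks. Noise is
// variance-matched uniform, as in the LAMMPS Langevin thermostat.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -------

// xoshiro256++ (public-domain algorithm), seeded through splitmix64.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {           // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double centered() {       // in [-0.5, 0.5)
    return unif() - 0.5;
  }
  inline int pick(int n) {         // uniform integer in [0, n)
    return (int)(unif() * n);
  }
  // three centered uniforms in [-0.5, 0.5) packed from one draw (21 bits each)
  inline void centered3(double& a, double& b, double& c) {
    const double s = 1.0 / 2097152.0;     // 2^-21
    uint64_t u = next();
    a = (double)(int64_t)( u        & 0x1FFFFFULL) * s - 0.5;
    b = (double)(int64_t)((u >> 21) & 0x1FFFFFULL) * s - 0.5;
    c = (double)(int64_t)((u >> 42) & 0x1FFFFFULL) * s - 0.5;
  }
};

// ------------------------------------------------------------- forces -------

struct ChainParams {
  double dt, kT, gamma, mass;
  double eps, sigma, feneK, feneR0, kTheta;
  double rc2;        // squared LJ cutoff
  double fcap;       // per-component force cap (soft-start safety)
  bool   anchored;   // beads 0 and N-1 frozen
  bool   overdamped; // Euler-Maruyama instead of BAOAB
};

static ChainParams readChainParams(const List& par) {
  ChainParams p;
  p.dt     = as<double>(par["dt"]);
  p.kT     = as<double>(par["kT"]);
  p.gamma  = as<double>(par["gamma"]);
  p.mass   = 1.0;
  p.eps    = as<double>(par["eps"]);
  p.sigma  = as<double>(par["sigma"]);
  p.feneK  = as<double>(par["feneK"]);
  p.feneR0 = as<double>(par["feneR0"]);
  p.kTheta = as<double>(par["kTheta"]);
  double rc = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  p.rc2    = rc * rc;
  p.fcap   = 1000.0;
  p.anchored = as<bool>(par["anchored"]);
  p.overdamped = as<bool>(par["overdamped"]);
  return p;
}

struct Engine {
  int N;
  ChainParams p;
  std::vector<double> x, y, z, fx, fy, fz, vx, vy, vz;
  // per-bond scratch (vectorizable division/sqrt loops)
  std::vector<double> bdx, bdy, bdz, br2, binvr2, binvl, binvu;
  // Verlet list for non-bonded WCA pairs (|i-j| > 1)
  std::vector<int> nlist;            // flattened pair list (i, j)
  std::vector<double> x0, y0, z0;    // positions at last rebuild
  double skin, skinHalf2;
  long long step = 0;
  bool haveForces = false;

  Engine(const NumericMatrix& coords, const ChainParams& par)
    : N(coords.nrow()), p(par),
      x(N), y(N), z(N), fx(N), fy(N), fz(N),
      vx(N, 0.0), vy(N, 0.0), vz(N, 0.0),
      bdx(N - 1), bdy(N - 1), bdz(N - 1), br2(N - 1),
      binvr2(N - 1), binvl(N - 1), binvu(N - 1),
      x0(N), y0(N), z0(N) {
    for (int i = 0; i < N; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    }
    skin = 1.5 * p.sigma;
    skinHalf2 = 0.25 * (skin - 0.15) * (skin - 0.15);
    rebuild();
  }

  // cell-list rebuild of the Verlet pair list, O(N)
  std::vector<int> cellHead, cellNext;
  void rebuild() {
    nlist.clear();
    double rl = std::sqrt(p.rc2) + skin;
    double rl2 = rl * rl;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < N; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
      if (z[i] < zmin) zmin = z[i];
      if (z[i] > zmax) zmax = z[i];
    }
    int nx = std::max(1, (int)((xmax - xmin) / rl));
    int ny = std::max(1, (int)((ymax - ymin) / rl));
    int nz = std::max(1, (int)((zmax - zmin) / rl));
    double cw_x = (xmax - xmin) / nx + 1e-12;
    double cw_y = (ymax - ymin) / ny + 1e-12;
    double cw_z = (zmax - zmin) / nz + 1e-12;
    int nc = nx * ny * nz;
    cellHead.assign(nc, -1);
    cellNext.assign(N, -1);
    std::vector<int> cix(N), ciy(N), ciz(N);
    for (int i = 0; i < N; ++i) {
      int cx = std::min(nx - 1, (int)((x[i] - xmin) / cw_x));
      int cy = std::min(ny - 1, (int)((y[i] - ymin) / cw_y));
      int cz = std::min(nz - 1, (int)((z[i] - zmin) / cw_z));
      cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
      int c = (cz * ny + cy) * nx + cx;
      cellNext[i] = cellHead[c]; cellHead[c] = i;
    }
    for (int i = 0; i < N; ++i) {
      for (int dcz = -1; dcz <= 1; ++dcz) {
        int cz = ciz[i] + dcz; if (cz < 0 || cz >= nz) continue;
        for (int dcy = -1; dcy <= 1; ++dcy) {
          int cy = ciy[i] + dcy; if (cy < 0 || cy >= ny) continue;
          for (int dcx = -1; dcx <= 1; ++dcx) {
            int cx = cix[i] + dcx; if (cx < 0 || cx >= nx) continue;
            int j = cellHead[(cz * ny + cy) * nx + cx];
            for (; j >= 0; j = cellNext[j]) {
              if (j <= i + 1) continue;          // i < j and |i-j| > 1
              double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              if (dx * dx + dy * dy + dz * dz < rl2) {
                nlist.push_back(i); nlist.push_back(j);
              }
            }
          }
        }
      }
    }
    x0 = x; y0 = y; z0 = z;
  }

  inline bool needRebuild() const {
    double m = 0.0;
    for (int i = 0; i < N; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m) m = d2;
    }
    return m > skinHalf2;
  }

  // WCA pair force magnitude / r (i.e. multiply by the separation vector)
  inline double wcaFr(double r2) const {
    double s2 = p.sigma * p.sigma / r2;
    double s6 = s2 * s2 * s2;
    return 24.0 * p.eps * s6 * (2.0 * s6 - 1.0) / r2;
  }

  bool computeForces() {
    const double R02 = p.feneR0 * p.feneR0;
    const double sig2 = p.sigma * p.sigma;
    const int nb = N - 1;
    for (int i = 0; i < nb; ++i) {
      bdx[i] = x[i + 1] - x[i];
      bdy[i] = y[i + 1] - y[i];
      bdz[i] = z[i + 1] - z[i];
      br2[i] = bdx[i] * bdx[i] + bdy[i] * bdy[i] + bdz[i] * bdz[i];
    }
    for (int i = 0; i < nb; ++i)
      if (br2[i] >= R02) return false;           // bond overstretch -> abort
    for (int i = 0; i < nb; ++i) binvr2[i] = 1.0 / br2[i];
    for (int i = 0; i < nb; ++i) binvu[i] = 1.0 / (R02 - br2[i]);
    for (int i = 0; i < nb; ++i) binvl[i] = std::sqrt(binvr2[i]);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // bonds: FENE + WCA between consecutive beads
    for (int i = 0; i < nb; ++i) {
      double fr = -p.feneK * R02 * binvu[i];     // attractive
      if (br2[i] < p.rc2) {
        double s2 = sig2 * binvr2[i];
        double s6 = s2 * s2 * s2;
        fr += 24.0 * p.eps * s6 * (2.0 * s6 - 1.0) * binvr2[i];
      }
      fx[i] -= fr * bdx[i]; fy[i] -= fr * bdy[i]; fz[i] -= fr * bdz[i];
      fx[i + 1] += fr * bdx[i]; fy[i + 1] += fr * bdy[i]; fz[i + 1] += fr * bdz[i];
    }
    // bending: U = kTheta (1 - cos theta), theta = 0 for a straight chain
    if (p.kTheta > 0.0) {
      for (int i = 1; i < N - 1; ++i) {
        const int a = i - 1, b = i;
        double ilab = binvl[a] * binvl[b];
        double c = (bdx[a] * bdx[b] + bdy[a] * bdy[b] + bdz[a] * bdz[b]) * ilab;
        double ca = c * binvr2[a], cb = c * binvr2[b];
        // F = kTheta * grad(cos theta)
        double g1x = p.kTheta * (bdx[b] * ilab - bdx[a] * ca);
        double g1y = p.kTheta * (bdy[b] * ilab - bdy[a] * ca);
        double g1z = p.kTheta * (bdz[b] * ilab - bdz[a] * ca);
        double g2x = p.kTheta * (bdx[a] * ilab - bdx[b] * cb);
        double g2y = p.kTheta * (bdy[a] * ilab - bdy[b] * cb);
        double g2z = p.kTheta * (bdz[a] * ilab - bdz[b] * cb);
        fx[i - 1] -= g1x; fy[i - 1] -= g1y; fz[i - 1] -= g1z;
        fx[i + 1] += g2x; fy[i + 1] += g2y; fz[i + 1] += g2z;
        fx[i] += g1x - g2x; fy[i] += g1y - g2y; fz[i] += g1z - g2z;
      }
    }
    // non-bonded WCA
    for (size_t k = 0; k < nlist.size(); k += 2) {
      int i = nlist[k], j = nlist[k + 1];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < p.rc2) {
        double fr = wcaFr(r2);
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    return true;
  }

  // capped steepest-descent quench with a tiny step: relieves excluded-volume
  // overlaps of freshly built coil configurations before thermal dynamics
  void softRelax(long long nSteps) {
    const double mob = 2e-4, cap = 100.0;
    const int lo = p.anchored ? 1 : 0;
    const int hi = p.anchored ? N - 1 : N;
    for (long long s = 0; s < nSteps; ++s) {
      if (needRebuild()) rebuild();
      computeForcesSoft();
      for (int i = lo; i < hi; ++i) {
        double gx = fx[i], gy = fy[i], gz = fz[i];
        if (gx >  cap) gx =  cap;
        if (gx < -cap) gx = -cap;
        if (gy >  cap) gy =  cap;
        if (gy < -cap) gy = -cap;
        if (gz >  cap) gz =  cap;
        if (gz < -cap) gz = -cap;
        x[i] += gx * mob; y[i] += gy * mob; z[i] += gz * mob;
      }
    }
    haveForces = false;
  }

  // force routine without the overstretch abort (bonds may start long)
  void computeForcesSoft() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    const double R02 = p.feneR0 * p.feneR0;
    for (int i = 0; i < N - 1; ++i) {
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      double u = 1.0 - r2 / R02;
      if (u < 0.02) u = 0.02;                    // linearized beyond R0
      double fr = -p.feneK / u;
      if (r2 < p.rc2 && r2 > 1e-8) fr += wcaFr(r2);
      fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
      fx[i + 1] += fr * dx; fy[i + 1] += fr * dy; fz[i + 1] += fr * dz;
    }
    for (size_t k = 0; k < nlist.size(); k += 2) {
      int i = nlist[k], j = nlist[k + 1];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < p.rc2 && r2 > 1e-8) {
        double fr = wcaFr(r2);
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
  }

  inline double capped(double f) const {
    if (f >  p.fcap) return  p.fcap;
    if (f < -p.fcap) return -p.fcap;
    return f;
  }

  // returns false on instability (bond overstretch)
  bool advance(long long nSteps, Xoshiro& rng) {
    const int lo = p.anchored ? 1 : 0;
    const int hi = p.anchored ? N - 1 : N;
    if (p.overdamped) {
      const double mob = p.dt / p.gamma;
      const double amp = std::sqrt(24.0 * p.kT * p.dt / p.gamma);
      for (long long s = 0; s < nSteps; ++s) {
        if (needRebuild()) rebuild();
        if (!computeForces()) return false;
        for (int i = lo; i < hi; ++i) {
          double n1, n2, n3;
          rng.centered3(n1, n2, n3);
          x[i] += capped(fx[i]) * mob + amp * n1;
          y[i] += capped(fy[i]) * mob + amp * n2;
          z[i] += capped(fz[i]) * mob + amp * n3;
        }
        ++step;
      }
      haveForces = false;
      return true;
    }
    // BAOAB Langevin: half-kick, half-drift, OU noise, half-drift, half-kick
    const double hdt = 0.5 * p.dt;
    const double hkick = hdt / p.mass;
    const double c1 = std::exp(-p.gamma * p.dt / p.mass);
    const double c2 = std::sqrt(p.kT * (1.0 - c1 * c1) / p.mass);
    if (!haveForces) {
      if (!computeForces()) return false;
      haveForces = true;
    }
    const double cn = c2 * std::sqrt(12.0);  // scale for centered uniforms
    for (long long s = 0; s < nSteps; ++s) {
      for (int i = lo; i < hi; ++i) {
        double n1, n2, n3;
        rng.centered3(n1, n2, n3);
        vx[i] += capped(fx[i]) * hkick;
        vy[i] += capped(fy[i]) * hkick;
        vz[i] += capped(fz[i]) * hkick;
        x[i] += vx[i] * hdt; y[i] += vy[i] * hdt; z[i] += vz[i] * hdt;
        vx[i] = c1 * vx[i] + cn * n1;
        vy[i] = c1 * vy[i] + cn * n2;
        vz[i] = c1 * vz[i] + cn * n3;
        x[i] += vx[i] * hdt; y[i] += vy[i] * hdt; z[i] += vz[i] * hdt;
      }
      if ((s & 3) == 0 && needRebuild()) rebuild();
      if (!computeForces()) return false;
      for (int i = lo; i < hi; ++i) {
        vx[i] += capped(fx[i]) * hkick;
        vy[i] += capped(fy[i]) * hkick;
        vz[i] += capped(fz[i]) * hkick;
      }
      ++step;
    }
    return true;
  }

  NumericMatrix coords() const {
    NumericMatrix m(N, 3);
    for (int i = 0; i < N; ++i) {
      m(i, 0) = x[i]; m(i, 1) = y[i]; m(i, 2) = z[i];
    }
    return m;
  }
};

// ------------------------------------------------------- exported API -------

// Plain chain run, sampling coordinates every `stride` steps.
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix coords0, List par, double nSteps, double stride,
                int seed) {
  ChainParams p = readChainParams(par);
  Engine eng(coords0, p);
  Xoshiro rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 1ULL);
  long long soft = (long long)as<double>(par["softSteps"]);
  if (soft > 0) eng.softRelax(soft);
  long long total = (long long)nSteps;
  long long str = (long long)stride;
  if (str < 1) str = 1;
  int nFrames = (int)(total / str);
  NumericVector traj((R_xlen_t)nFrames * coords0.nrow() * 3);
  traj.attr("dim") = IntegerVector::create(coords0.nrow(), 3, nFrames);
  long long done = 0;
  int frame = 0;
  while (done < total) {
    long long chunk = std::min(str, total - done);
    if (!eng.advance(chunk, rng)) {
      List out = List::create(_["ok"] = false, _["failStep"] = (double)eng.step,
                              _["coords"] = eng.coords());
      return out;
    }
    done += chunk;
    if (done % str == 0 && frame < nFrames) {
      NumericMatrix c = eng.coords();
      for (int i = 0; i < c.nrow(); ++i)
        for (int d = 0; d < 3; ++d)
          traj[(R_xlen_t)frame * c.nrow() * 3 + d * c.nrow() + i] = c(i, d);
      ++frame;
    }
  }
  return List::create(_["ok"] = true, _["traj"] = traj,
                      _["coords"] = eng.coords(), _["nFrames"] = frame);
}

// Energy decomposition of a configuration (for cross-checks against the
// R-level closed-form potentials).
// [[Rcpp::export]]
List cpp_chain_energy(NumericMatrix coords, List par) {
  ChainParams p = readChainParams(par);
  int N = coords.nrow();
  double eFene = 0.0, eWca = 0.0, eBend = 0.0;
  const double R02 = p.feneR0 * p.feneR0;
  double shift = p.eps; // 4 eps * 1/4 at the cutoff
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < p.rc2) {
        double s2 = p.sigma * p.sigma / r2, s6 = s2 * s2 * s2;
        eWca += 4.0 * p.eps * (s6 * s6 - s6) + shift;
      }
      if (j == i + 1) {
        eFene += -0.5 * p.feneK * R02 * std::log(1.0 - r2 / R02);
      }
    }
  }
  for (int i = 1; i < N - 1; ++i) {
    double ax = coords(i, 0) - coords(i - 1, 0);
    double ay = coords(i, 1) - coords(i - 1, 1);
    double az = coords(i, 2) - coords(i - 1, 2);
    double bx = coords(i + 1, 0) - coords(i, 0);
    double by = coords(i + 1, 1) - coords(i, 1);
    double bz = coords(i + 1, 2) - coords(i, 2);
    double c = (ax * bx + ay * by + az * bz) /
      std::sqrt((ax * ax + ay * ay + az * az) * (bx * bx + by * by + bz * bz));
    eBend += p.kTheta * (1.0 - c);
  }
  return List::create(_["fene"] = eFene, _["wca"] = eWca, _["bend"] = eBend);
}

// ---------------------------------------------- coupled ParB simulation -----

// Lattice occupancy lives on the beads. Every `updateEvery` integration steps
// each loaded ParB attempts one +-1 hop with total probability moveProb, then
// with probability recruitProb triggers a recruitment attempt that is in cis
// with probability pCis and otherwise in trans (3D-proximal, 1D-distant).
// [[Rcpp::export]]
List cpp_run_coupled(NumericMatrix coords0, List par, List parb, int seed) {
  ChainParams p = readChainParams(par);
  Engine eng(coords0, p);
  Xoshiro rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 1ULL);
  long long soft = (long long)as<double>(par["softSteps"]);
  if (soft > 0) eng.softRelax(soft);
  int N = coords0.nrow();

  long long updateEvery = (long long)as<double>(parb["updateEvery"]);
  long long nUpdates    = (long long)as<double>(parb["nUpdates"]);
  long long eqSteps     = (long long)as<double>(parb["eqSteps"]);
  double moveProb    = as<double>(parb["moveProb"]);
  double recruitProb = as<double>(parb["recruitProb"]);
  double pCis        = as<double>(parb["pCis"]);
  double cutoff      = as<double>(parb["transCutoff"]); // sigma units
  int    transExcl   = as<int>(parb["transExcl"]);      // 1D exclusion (2)
  int    parsIdx     = as<int>(parb["parsIndex"]);      // 0-based
  int    rbIdx       = as<int>(parb["rbIndex"]);        // 0-based, -1 = none
  long long sampleEvery = (long long)as<double>(parb["sampleEvery"]);
  double cutoff2 = cutoff * cutoff;

  std::vector<int> occ(N, 0);
  std::vector<int> parbs;           // bead index of each loaded ParB
  std::vector<int> evType, evSrc, evDst; // 0 load, 1 cis, 2 trans, 3 failed
  std::vector<double> evTime;       // in updates
  long long moveAttempts = 0, moveAccepted = 0;
  bool bypass = false;

  if (eqSteps > 0 && !eng.advance(eqSteps, rng))
    return List::create(_["ok"] = false, _["failStep"] = (double)eng.step);

  // initial load at parS
  occ[parsIdx] = 1;
  parbs.push_back(parsIdx);
  evType.push_back(0); evSrc.push_back(NA_INTEGER);
  evDst.push_back(parsIdx); evTime.push_back(0.0);

  int nSamples = (int)(nUpdates / sampleEvery) + 1;
  IntegerMatrix occupancy(nSamples, N);
  for (int j = 0; j < N; ++j) occupancy(0, j) = occ[j];
  int sampleRow = 1;

  std::vector<int> elig;
  for (long long u = 1; u <= nUpdates; ++u) {
    if (!eng.advance(updateEvery, rng))
      return List::create(_["ok"] = false, _["failStep"] = (double)eng.step);

    // diffusion: each ParB attempts one hop
    for (size_t k = 0; k < parbs.size(); ++k) {
      ++moveAttempts;
      if (rng.unif() >= moveProb) continue;
      int i = parbs[k];
      int j = i + (rng.unif() < 0.5 ? -1 : 1);
      if (j < 0 || j >= N || occ[j] || j == rbIdx) continue; // rejected
      occ[i] = 0; occ[j] = 1; parbs[k] = j;
      ++moveAccepted;
    }

    // recruitment
    size_t nLoaded = parbs.size();
    for (size_t k = 0; k < nLoaded; ++k) {
      if (rng.unif() >= recruitProb) continue;
      int i = parbs[k];
      if (rng.unif() < pCis) {
        int j = i + (rng.unif() < 0.5 ? -1 : 1);
        if (j >= 0 && j < N && !occ[j] && j != rbIdx) {
          occ[j] = 1; parbs.push_back(j);
          evType.push_back(1); evSrc.push_back(i); evDst.push_back(j);
          evTime.push_back((double)u);
        } else {
          evType.push_back(3); evSrc.push_back(i); evDst.push_back(NA_INTEGER);
          evTime.push_back((double)u);
        }
      } else {
        elig.clear();
        double xi = eng.x[i], yi = eng.y[i], zi = eng.z[i];
        for (int j = 0; j < N; ++j) {
          if (std::abs(j - i) <= transExcl || occ[j] || j == rbIdx) continue;
          double dx = eng.x[j] - xi, dy = eng.y[j] - yi, dz = eng.z[j] - zi;
          if (dx * dx + dy * dy + dz * dz <= cutoff2) elig.push_back(j);
        }
        if (elig.empty()) {
          evType.push_back(3); evSrc.push_back(i); evDst.push_back(NA_INTEGER);
          evTime.push_back((double)u);
        } else {
          int j = elig[rng.pick((int)elig.size())];
          occ[j] = 1; parbs.push_back(j);
          evType.push_back(2); evSrc.push_back(i); evDst.push_back(j);
          evTime.push_back((double)u);
        }
      }
    }

    // sticky bypass flag: any ParB strictly beyond the roadblock
    if (!bypass && rbIdx >= 0) {
      for (size_t k = 0; k < parbs.size(); ++k)
        if (parbs[k] > rbIdx) { bypass = true; break; }
    }
    if (u % sampleEvery == 0 && sampleRow < nSamples) {
      for (int j = 0; j < N; ++j) occupancy(sampleRow, j) = occ[j];
      ++sampleRow;
    }
  }

  return List::create(
    _["ok"] = true,
    _["occupancy"] = occupancy,
    _["eventType"] = IntegerVector(evType.begin(), evType.end()),
    _["eventSrc"]  = IntegerVector(evSrc.begin(), evSrc.end()),
    _["eventDst"]  = IntegerVector(evDst.begin(), evDst.end()),
    _["eventTime"] = NumericVector(evTime.begin(), evTime.end()),
    _["bypass"] = bypass,
    _["moveAttempts"] = (double)moveAttempts,
    _["moveAccepted"] = (double)moveAccepted,
    _["nParB"] = (int)parbs.size(),
    _["coords"] = eng.coords());
}
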