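// Core numerics for the minimalistic coarse-grained (mCG) amphiphile model:
// truncated-shifted Lennard-Jones + harmonic bonds under cubic PBC, a
// cell-built Verlet neighbour list (0.3 nm skin, displacement-triggered
// rebuild), a BAOAB Langevin integrator and a steepest-descent relaxer.
// Units follow the GROMACS convention: nm, ps, kJ/mol, amu (g/mol).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <array>

using namespace Rcpp;

static const double KB = 0.00831446261815324; // kJ mol^-1 K^-1

struct PairParams {
  int ntype;
  std::vector<double> s2;    // sigma^2 per type pair
  std::vector<double> eps;   // epsilon per type pair
  std::vector<double> shift; // 4*eps*((s/rc)^12-(s/rc)^6), subtracted below rc
  double rc, rc2;
  bool any_lj;
};

static PairParams make_pair_params(const NumericMatrix& sigma,
                                   const NumericMatrix& eps,
                                   double rc) {
  PairParams pp;
  pp.ntype = sigma.nrow();
  pp.rc = rc;
  pp.rc2 = rc * rc;
  pp.s2.resize(pp.ntype * pp.ntype);
  pp.eps.resize(pp.ntype * pp.ntype);
  pp.shift.resize(pp.ntype * pp.ntype);
  pp.any_lj = false;
  for (int a = 0; a < pp.ntype; ++a) {
    for (int b = 0; b < pp.ntype; ++b) {
      double s = sigma(a, b), e = eps(a, b);
      double sr6 = std::pow(s * s / pp.rc2, 3.0);
      pp.s2[a * pp.ntype + b] = s * s;
      pp.eps[a * pp.ntype + b] = e;
      pp.shift[a * pp.ntype + b] = 4.0 * e * (sr6 * sr6 - sr6);
      if (e > 0.0) pp.any_lj = true;
    }
  }
  return pp;
}

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double wrap0L(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against floor round-off at the boundary
  return x;
}

// bonded (1-2) exclusion table: at most 2 partners per bead in a linear chain
struct Exclusions {
  std::vector<std::array<int, 2> > partner;
  void build(int n, const IntegerMatrix& bonds) {
    partner.assign(n, std::array<int, 2>{{-1, -1}});
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      add(i, j); add(j, i);
    }
  }
  void add(int i, int j) {
    if (partner[i][0] < 0) partner[i][0] = j;
    else partner[i][1] = j;
  }
  inline bool excluded(int i, int j) const {
    return partner[i][0] == j || partner[i][1] == j;
  }
};

// Verlet pair list within rc + skin, built through a cell list.
struct NeighbourList {
  std::vector<int> pi, pj;      // pair bead indices
  std::vector<double> rx, ry, rz; // positions at build time
  double skin;

  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, double L, double rlist,
             const Exclusions& excl) {
    const int n = (int)px.size();
    pi.clear(); pj.clear();
    rx = px; ry = py; rz = pz;
    double rl2 = rlist * rlist;
    int nc = (int)std::floor(L / rlist);
    if (nc < 3) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (excl.excluded(i, j)) continue;
          double dx = min_image(px[i] - px[j], L);
          double dy = min_image(py[i] - py[j], L);
          double dz = min_image(pz[i] - pz[j], L);
          if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
        }
      return;
    }
    double cell = L / nc;
    int ncell3 = nc * nc * nc;
    std::vector<int> head(ncell3, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int ix = (int)(px[i] / cell); if (ix >= nc) ix = nc - 1; if (ix < 0) ix = 0;
      int iy = (int)(py[i] / cell); if (iy >= nc) iy = nc - 1; if (iy < 0) iy = 0;
      int iz = (int)(pz[i] / cell); if (iz >= nc) iz = nc - 1; if (iz < 0) iz = 0;
      int c = (ix * nc + iy) * nc + iz;
      nxt[i] = head[c]; head[c] = i;
    }
    static const int OFF[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int ix = 0; ix < nc; ++ix)
    for (int iy = 0; iy < nc; ++iy)
    for (int iz = 0; iz < nc; ++iz) {
      int c = (ix * nc + iy) * nc + iz;
      if (head[c] < 0) continue;
      for (int i = head[c]; i >= 0; i = nxt[i])
        for (int j = nxt[i]; j >= 0; j = nxt[j]) {
          if (excl.excluded(i, j)) continue;
          double dx = min_image(px[i] - px[j], L);
          double dy = min_image(py[i] - py[j], L);
          double dz = min_image(pz[i] - pz[j], L);
          if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
        }
      for (int k = 0; k < 13; ++k) {
        int jx = (ix + OFF[k][0] + nc) % nc;
        int jy = (iy + OFF[k][1] + nc) % nc;
        int jz = (iz + OFF[k][2] + nc) % nc;
        int c2 = (jx * nc + jy) * nc + jz;
        if (head[c2] < 0) continue;
        for (int i = head[c]; i >= 0; i = nxt[i])
          for (int j = head[c2]; j >= 0; j = nxt[j]) {
            if (excl.excluded(i, j)) continue;
            double dx = min_image(px[i] - px[j], L);
            double dy = min_image(py[i] - py[j], L);
            double dz = min_image(pz[i] - pz[j], L);
            if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
          }
      }
    }
  }

  // max squared displacement since build; rebuild when any bead moved > skin/2
  bool stale(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, double L) const {
    double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < px.size(); ++i) {
      double dx = min_image(px[i] - rx[i], L);
      double dy = min_image(py[i] - ry[i], L);
      double dz = min_image(pz[i] - rz[i], L);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// Force/energy evaluation over a pair list (pairs are within rc + skin).
static double eval_forces(const std::vector<double>& px,
                          const std::vector<double>& py,
                          const std::vector<double>& pz,
                          const std::vector<int>& type,
                          const PairParams& pp,
                          double L,
                          const IntegerMatrix& bonds,
                          double r0, double kb,
                          const NeighbourList& nl,
                          std::vector<double>& fx,
                          std::vector<double>& fy,
                          std::vector<double>& fz,
                          int* n_clamped) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double epot = 0.0;
  const double rmin2 = 1e-12; // 1e-6 nm overlap floor

  if (pp.any_lj) {
    const size_t np = nl.pi.size();
    for (size_t p = 0; p < np; ++p) {
      int i = nl.pi[p], j = nl.pj[p];
      double dx = min_image(px[i] - px[j], L);
      double dy = min_image(py[i] - py[j], L);
      double dz = min_image(pz[i] - pz[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pp.rc2) continue;
      if (r2 < rmin2) { r2 = rmin2; if (n_clamped) ++(*n_clamped); }
      int tp = type[i] * pp.ntype + type[j];
      double e = pp.eps[tp];
      if (e == 0.0) continue;
      double sr2 = pp.s2[tp] / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      epot += 4.0 * e * (sr12 - sr6) - pp.shift[tp];
      double fmag = 24.0 * e * (2.0 * sr12 - sr6) / r2;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }

  // harmonic bonds: E = 0.5 kb (r - r0)^2
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = min_image(px[i] - px[j], L);
    double dy = min_image(py[i] - py[j], L);
    double dz = min_image(pz[i] - pz[j], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) r = 1e-9;
    double dr = r - r0;
    epot += 0.5 * kb * dr * dr;
    double fmag = -kb * dr / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }
  return epot;
}

static void unpack(const NumericMatrix& m, std::vector<double>& x,
                   std::vector<double>& y, std::vector<double>& z) {
  int n = m.nrow();
  x.resize(n); y.resize(n); z.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = m(i, 0); y[i] = m(i, 1); z[i] = m(i, 2); }
}

static NumericMatrix pack(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z) {
  int n = (int)x.size();
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) { m(i, 0) = x[i]; m(i, 1) = y[i]; m(i, 2) = z[i]; }
  return m;
}

static const double SKIN = 0.3; // nm

// [[Rcpp::export]]
List forces_cpp(NumericMatrix pos, IntegerVector type,
                NumericMatrix sigma, NumericMatrix eps, double rc,
                double L, IntegerMatrix bonds, double r0, double kb) {
  int n = pos.nrow();
  std::vector<double> px, py, pz, fx(n), fy(n), fz(n);
  unpack(pos, px, py, pz);
  for (int i = 0; i < n; ++i) {
    px[i] = wrap0L(px[i], L); py[i] = wrap0L(py[i], L); pz[i] = wrap0L(pz[i], L);
  }
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;
  PairParams pp = make_pair_params(sigma, eps, rc);
  Exclusions excl; excl.build(n, bonds);
  NeighbourList nl; nl.skin = SKIN;
  if (pp.any_lj) nl.build(px, py, pz, L, rc + SKIN, excl);
  int ncl = 0;
  double epot = eval_forces(px, py, pz, ty, pp, L, bonds, r0, kb, nl,
                            fx, fy, fz, &ncl);
  return List::create(_["forces"] = pack(fx, fy, fz),
                      _["epot"] = epot,
                      _["n_clamped"] = ncl);
}

// BAOAB Langevin integrator; thermal noise drawn from R's RNG so that
// set.seed() in R gives bitwise-reproducible trajectories.
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                NumericMatrix sigma, NumericMatrix eps, double rc,
                double L, IntegerMatrix bonds, double r0, double kb,
                NumericVector mass, double dt, double gamma, double temp,
                int nsteps, int stride, double t0) {
  int n = pos.nrow();
  std::vector<double> px, py, pz, vx, vy, vz, fx(n), fy(n), fz(n);
  unpack(pos, px, py, pz);
  unpack(vel, vx, vy, vz);
  for (int i = 0; i < n; ++i) {
    px[i] = wrap0L(px[i], L); py[i] = wrap0L(py[i], L); pz[i] = wrap0L(pz[i], L);
  }
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;
  PairParams pp = make_pair_params(sigma, eps, rc);
  Exclusions excl; excl.build(n, bonds);
  NeighbourList nl; nl.skin = SKIN;
  if (pp.any_lj) nl.build(px, py, pz, L, rc + SKIN, excl);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> invm(n), sigv(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = 1.0 / mass[i];
    sigv[i] = std::sqrt(KB * temp * invm[i]);
  }

  int nclamp = 0;
  double epot = eval_forces(px, py, pz, ty, pp, L, bonds, r0, kb, nl,
                            fx, fy, fz, &nclamp);

  int nframes = (stride > 0 ? nsteps / stride : 0) + 1;
  List frames(nframes);
  NumericVector times(nframes), epots(nframes), temps(nframes);
  RNGScope rng;

  auto kinT = [&]() {
    double k2 = 0.0;
    for (int i = 0; i < n; ++i)
      k2 += mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return k2 / (3.0 * n * KB);
  };

  int fr = 0;
  frames[fr] = pack(px, py, pz);
  times[fr] = t0; epots[fr] = epot; temps[fr] = kinT();
  ++fr;

  const double hdt = 0.5 * dt;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) { // B
      vx[i] += hdt * fx[i] * invm[i];
      vy[i] += hdt * fy[i] * invm[i];
      vz[i] += hdt * fz[i] * invm[i];
    }
    for (int i = 0; i < n; ++i) { // A
      px[i] += hdt * vx[i]; py[i] += hdt * vy[i]; pz[i] += hdt * vz[i];
    }
    if (c2 > 0.0) { // O (skipped exactly in the gamma -> 0 NVE limit)
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * sigv[i] * norm_rand();
        vy[i] = c1 * vy[i] + c2 * sigv[i] * norm_rand();
        vz[i] = c1 * vz[i] + c2 * sigv[i] * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) { // A
      px[i] += hdt * vx[i]; py[i] += hdt * vy[i]; pz[i] += hdt * vz[i];
      px[i] = wrap0L(px[i], L); py[i] = wrap0L(py[i], L); pz[i] = wrap0L(pz[i], L);
    }
    if (pp.any_lj && nl.stale(px, py, pz, L))
      nl.build(px, py, pz, L, pp.rc + SKIN, excl);
    epot = eval_forces(px, py, pz, ty, pp, L, bonds, r0, kb, nl,
                       fx, fy, fz, &nclamp);
    for (int i = 0; i < n; ++i) { // B
      vx[i] += hdt * fx[i] * invm[i];
      vy[i] += hdt * fy[i] * invm[i];
      vz[i] += hdt * fz[i] * invm[i];
    }
    if (!std::isfinite(epot) || !std::isfinite(px[0]))
      stop("integration blow-up (non-finite coordinates/energy) at step %d", step);
    if (stride > 0 && step % stride == 0) {
      frames[fr] = pack(px, py, pz);
      times[fr] = t0 + step * dt; epots[fr] = epot; temps[fr] = kinT();
      ++fr;
    }
    if (step % 2000 == 0) checkUserInterrupt();
  }

  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epots, _["temp"] = temps,
                      _["pos"] = pack(px, py, pz),
                      _["vel"] = pack(vx, vy, vz),
                      _["n_clamped"] = nclamp);
}

// Steepest-descent relaxation with a displacement cap; used to remove bad
// contacts in freshly built systems before dynamics.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix pos, IntegerVector type,
                  NumericMatrix sigma, NumericMatrix eps, double rc,
                  double L, IntegerMatrix bonds, double r0, double kb,
                  int nsteps, double max_disp) {
  int n = pos.nrow();
  std::vector<double> px, py, pz, fx(n), fy(n), fz(n);
  unpack(pos, px, py, pz);
  for (int i = 0; i < n; ++i) {
    px[i] = wrap0L(px[i], L); py[i] = wrap0L(py[i], L); pz[i] = wrap0L(pz[i], L);
  }
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;
  PairParams pp = make_pair_params(sigma, eps, rc);
  Exclusions excl; excl.build(n, bonds);
  NeighbourList nl; nl.skin = SKIN;
  double step = max_disp;
  if (pp.any_lj) nl.build(px, py, pz, L, pp.rc + SKIN, excl);
  double epot = eval_forces(px, py, pz, ty, pp, L, bonds, r0, kb, nl,
                            fx, fy, fz, nullptr);
  for (int it = 0; it < nsteps; ++it) {
    double fmax = 1e-30;
    for (int i = 0; i < n; ++i) {
      double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i]);
      if (f > fmax) fmax = f;
    }
    double scl = step / fmax;
    std::vector<double> qx(px), qy(py), qz(pz);
    for (int i = 0; i < n; ++i) {
      qx[i] = wrap0L(px[i] + scl * fx[i], L);
      qy[i] = wrap0L(py[i] + scl * fy[i], L);
      qz[i] = wrap0L(pz[i] + scl * fz[i], L);
    }
    if (pp.any_lj && nl.stale(qx, qy, qz, L))
      nl.build(qx, qy, qz, L, pp.rc + SKIN, excl);
    std::vector<double> gx(n), gy(n), gz(n);
    double enew = eval_forces(qx, qy, qz, ty, pp, L, bonds, r0, kb, nl,
                              gx, gy, gz, nullptr);
    if (enew < epot) {
      px.swap(qx); py.swap(qy); pz.swap(qz);
      fx.swap(gx); fy.swap(gy); fz.swap(gz);
      epot = enew;
      step = std::min(step * 1.2, max_disp);
    } else {
      step *= 0.5;
      if (step < 1e-8) break;
    }
  }
  return List::create(_["pos"] = pack(px, py, pz), _["epot"] = epot);
}
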