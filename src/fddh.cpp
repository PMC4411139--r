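#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shrake-Rupley solvent-accessible surface area
// ---------------------------------------------------------------------------

// Deterministic quasi-uniform sphere points (golden-spiral lattice).
static void sphere_points(int n, std::vector<double> &px, std::vector<double> &py,
                          std::vector<double> &pz) {
  px.resize(n); py.resize(n); pz.resize(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    px[i] = r * std::cos(th);
    py[i] = r * std::sin(th);
    pz[i] = z;
  }
}

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe,
                       int n_points, IntegerVector subset) {
  int n = xyz.nrow();
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  NumericVector out(subset.size());
  for (int si = 0; si < subset.size(); ++si) {
    int i = subset[si] - 1;
    double ri = radii[i] + probe;
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    // neighbours that can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = ri + rj;
      if (d2 < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double x = xi + ri * px[p], y = yi + ri * py[p], z = zi + ri * pz[p];
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double rj = radii[j] + probe;
        double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[si] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Finite-difference linearized Poisson-Boltzmann solver
// ---------------------------------------------------------------------------

struct Grid3 {
  int nx, ny, nz;
  inline long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
};

// Build the solvent-excluded "inside" mask on a half-spacing lattice so that
// both grid nodes and edge midpoints can be classified from one field.
// Lattice point (a,b,c) with a in 0..2(nx-1) sits at origin + a*h/2.
static void build_inside_mask(const NumericMatrix &axyz, const NumericVector &arad,
                              double probe, const std::vector<double> &origin,
                              double h, const Grid3 &g,
                              std::vector<uint8_t> &inside) {
  int fx = 2 * g.nx - 1, fy = 2 * g.ny - 1, fz = 2 * g.nz - 1;
  double hf = h / 2.0;
  long ntot = (long)fx * fy * fz;
  std::vector<uint8_t> infl(ntot, 0), vdw(ntot, 0);
  inside.assign(ntot, 0);
  int na = axyz.nrow();
  auto fidx = [&](int a, int b, int c) {
    return (long)a + (long)fx * ((long)b + (long)fy * (long)c);
  };
  // stamp inflated (r+probe) and vdW (r) spheres
  for (int t = 0; t < na; ++t) {
    double ax = axyz(t, 0), ay = axyz(t, 1), az = axyz(t, 2);
    double rin = arad[t] + probe, r2in = rin * rin;
    double rv = arad[t], r2v = rv * rv;
    int a0 = std::max(0, (int)std::floor((ax - rin - origin[0]) / hf));
    int a1 = std::min(fx - 1, (int)std::ceil((ax + rin - origin[0]) / hf));
    int b0 = std::max(0, (int)std::floor((ay - rin - origin[1]) / hf));
    int b1 = std::min(fy - 1, (int)std::ceil((ay + rin - origin[1]) / hf));
    int c0 = std::max(0, (int)std::floor((az - rin - origin[2]) / hf));
    int c1 = std::min(fz - 1, (int)std::ceil((az + rin - origin[2]) / hf));
    for (int c = c0; c <= c1; ++c) {
      double dz = origin[2] + c * hf - az, dz2 = dz * dz;
      for (int b = b0; b <= b1; ++b) {
        double dy = origin[1] + b * hf - ay, d2yz = dy * dy + dz2;
        if (d2yz > r2in) continue;
        for (int a = a0; a <= a1; ++a) {
          double dx = origin[0] + a * hf - ax;
          double d2 = dx * dx + d2yz;
          if (d2 <= r2in) {
            long id = fidx(a, b, c);
            infl[id] = 1;
            if (d2 <= r2v) vdw[id] = 1;
          }
        }
      }
    }
  }
  if (na == 0) return; // all solvent
  // reopen: lattice cells in the probe-accessible region carve back the
  // inflated mask (probe centres approximated by solvent cells adjacent to it)
  int pr = (int)std::ceil(probe / hf);
  double p2 = probe * probe;
  std::vector<uint8_t> reopened(ntot, 0);
  for (int c = 0; c < fz; ++c)
    for (int b = 0; b < fy; ++b)
      for (int a = 0; a < fx; ++a) {
        long id = fidx(a, b, c);
        if (infl[id]) continue; // solvent cell
        bool boundary = false;
        if (a > 0 && infl[fidx(a - 1, b, c)]) boundary = true;
        else if (a < fx - 1 && infl[fidx(a + 1, b, c)]) boundary = true;
        else if (b > 0 && infl[fidx(a, b - 1, c)]) boundary = true;
        else if (b < fy - 1 && infl[fidx(a, b + 1, c)]) boundary = true;
        else if (c > 0 && infl[fidx(a, b, c - 1)]) boundary = true;
        else if (c < fz - 1 && infl[fidx(a, b, c + 1)]) boundary = true;
        if (!boundary) continue;
        int aa0 = std::max(0, a - pr), aa1 = std::min(fx - 1, a + pr);
        int bb0 = std::max(0, b - pr), bb1 = std::min(fy - 1, b + pr);
        int cc0 = std::max(0, c - pr), cc1 = std::min(fz - 1, c + pr);
        for (int cc = cc0; cc <= cc1; ++cc) {
          double dz = (cc - c) * hf, dz2 = dz * dz;
          for (int bb = bb0; bb <= bb1; ++bb) {
            double dy = (bb - b) * hf, d2yz = dy * dy + dz2;
            if (d2yz > p2) continue;
            for (int aa = aa0; aa <= aa1; ++aa) {
              double dx = (aa - a) * hf;
              if (dx * dx + d2yz <= p2) {
                long id2 = fidx(aa, bb, cc);
                if (infl[id2] && !vdw[id2]) reopened[id2] = 1;
              }
            }
          }
        }
      }
  for (long i = 0; i < ntot; ++i) inside[i] = infl[i] && !reopened[i];
}

// Ion-accessibility mask on grid nodes: node is salt-free within r+stern.
static void build_ion_mask(const NumericMatrix &axyz, const NumericVector &arad,
                           double stern, const std::vector<double> &origin,
                           double h, const Grid3 &g, std::vector<uint8_t> &excl) {
  long ntot = (long)g.nx * g.ny * g.nz;
  excl.assign(ntot, 0);
  int na = axyz.nrow();
  for (int t = 0; t < na; ++t) {
    double ax = axyz(t, 0), ay = axyz(t, 1), az = axyz(t, 2);
    double r = arad[t] + stern, r2 = r * r;
    int a0 = std::max(0, (int)std::floor((ax - r - origin[0]) / h));
    int a1 = std::min(g.nx - 1, (int)std::ceil((ax + r - origin[0]) / h));
    int b0 = std::max(0, (int)std::floor((ay - r - origin[1]) / h));
    int b1 = std::min(g.ny - 1, (int)std::ceil((ay + r - origin[1]) / h));
    int c0 = std::max(0, (int)std::floor((az - r - origin[2]) / h));
    int c1 = std::min(g.nz - 1, (int)std::ceil((az + r - origin[2]) / h));
    for (int c = c0; c <= c1; ++c) {
      double dz = origin[2] + c * h - az, dz2 = dz * dz;
      for (int b = b0; b <= b1; ++b) {
        double dy = origin[1] + b * h - ay, d2yz = dy * dy + dz2;
        if (d2yz > r2) continue;
        for (int a = a0; a <= a1; ++a) {
          double dx = origin[0] + a * h - ax;
          if (dx * dx + d2yz <= r2) excl[g.idx(a, b, c)] = 1;
        }
      }
    }
  }
}

// Solve the linearized PB equation on one focusing level.
// phi0: initial grid (boundary values are held fixed); kT/e units throughout.
// Returns list(phi, iterations, max_update).
// [[Rcpp::export]]
List lpbe_level_cpp(NumericMatrix atom_xyz, NumericVector atom_rad,
                    NumericMatrix chg_xyz, NumericVector chg_q,
                    double eps_in, double eps_out, double kappa,
                    double probe, double stern,
                    IntegerVector dims, double h, NumericVector origin_,
                    NumericVector phi0, double coul_kT,
                    double tol, int max_iter) {
  Grid3 g; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  long ntot = (long)g.nx * g.ny * g.nz;
  std::vector<double> origin(3);
  for (int i = 0; i < 3; ++i) origin[i] = origin_[i];

  bool uniform = (atom_xyz.nrow() == 0) || (eps_in == eps_out);
  std::vector<uint8_t> inside;
  if (!uniform) build_inside_mask(atom_xyz, atom_rad, probe, origin, h, g, inside);
  std::vector<uint8_t> ion_excl;
  double kbar2 = eps_out * kappa * kappa * h * h; // screening term (grid units)
  if (kappa > 0.0 && atom_xyz.nrow() > 0)
    build_ion_mask(atom_xyz, atom_rad, stern, origin, h, g, ion_excl);

  int fx = 2 * g.nx - 1, fy = 2 * g.ny - 1;
  auto eps_mid = [&](int a, int b, int c) -> double {
    // half-lattice point (a,b,c)
    if (uniform) return eps_out;
    long id = (long)a + (long)fx * ((long)b + (long)fy * (long)c);
    return inside[id] ? eps_in : eps_out;
  };

  // charge spreading (trilinear) onto nodes
  std::vector<double> src(ntot, 0.0);
  double sfac = 4.0 * M_PI * coul_kT / h;
  for (int t = 0; t < chg_xyz.nrow(); ++t) {
    double gx = (chg_xyz(t, 0) - origin[0]) / h;
    double gy = (chg_xyz(t, 1) - origin[1]) / h;
    double gz = (chg_xyz(t, 2) - origin[2]) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= g.nx - 1 || j0 >= g.ny - 1 || k0 >= g.nz - 1)
      stop("charge outside grid");
    double fxw = gx - i0, fyw = gy - j0, fzw = gz - k0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fxw : 1 - fxw) * (dj ? fyw : 1 - fyw) * (dk ? fzw : 1 - fzw);
          src[g.idx(i0 + di, j0 + dj, k0 + dk)] += sfac * chg_q[t] * w;
        }
  }

  // precompute per-node face dielectrics and diagonal
  std::vector<float> exm(ntot), exp_(ntot), eym(ntot), eyp(ntot), ezm(ntot), ezp(ntot);
  std::vector<float> diag(ntot);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long id = g.idx(i, j, k);
        int a = 2 * i, b = 2 * j, c = 2 * k;
        double em = (i > 0) ? eps_mid(a - 1, b, c) : eps_out;
        double ep = (i < g.nx - 1) ? eps_mid(a + 1, b, c) : eps_out;
        double fm = (j > 0) ? eps_mid(a, b - 1, c) : eps_out;
        double fp = (j < g.ny - 1) ? eps_mid(a, b + 1, c) : eps_out;
        double gm = (k > 0) ? eps_mid(a, b, c - 1) : eps_out;
        double gp = (k < g.nz - 1) ? eps_mid(a, b, c + 1) : eps_out;
        exm[id] = em; exp_[id] = ep; eym[id] = fm; eyp[id] = fp; ezm[id] = gm; ezp[id] = gp;
        double kap = 0.0;
        if (kappa > 0.0) {
          bool accessible = ion_excl.empty() ? true : !ion_excl[id];
          if (accessible) kap = kbar2;
        }
        diag[id] = em + ep + fm + fp + gm + gp + kap;
      }

  std::vector<double> phi(phi0.begin(), phi0.end());
  int nmax = std::max(g.nx, std::max(g.ny, g.nz));
  double omega = 2.0 / (1.0 + std::sin(M_PI / nmax));
  double maxupd = 0.0;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    maxupd = 0.0;
    for (int rb = 0; rb < 2; ++rb) {
      for (int k = 1; k < g.nz - 1; ++k)
        for (int j = 1; j < g.ny - 1; ++j) {
          int istart = 1 + ((j + k + rb) % 2);
          for (int i = istart; i < g.nx - 1; i += 2) {
            long id = g.idx(i, j, k);
            double num = exm[id] * phi[id - 1] + exp_[id] * phi[id + 1]
                       + eym[id] * phi[id - g.nx] + eyp[id] * phi[id + g.nx]
                       + ezm[id] * phi[id - (long)g.nx * g.ny]
                       + ezp[id] * phi[id + (long)g.nx * g.ny]
                       + src[id];
            double nphi = num / diag[id];
            double upd = omega * (nphi - phi[id]);
            phi[id] += upd;
            double au = std::fabs(upd);
            if (au > maxupd) maxupd = au;
          }
        }
    }
    if (maxupd < tol) break;
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["iterations"] = iter, _["max_update"] = maxupd,
                      _["converged"] = (maxupd < tol));
}

// Debye-Hueckel monopole-sum boundary/initial values for a grid.
// only_boundary: fill just the 6 faces (interior left at 0).
// [[Rcpp::export]]
NumericVector dh_grid_cpp(NumericMatrix chg_xyz, NumericVector chg_q,
                          double eps, double kappa, IntegerVector dims,
                          double h, NumericVector origin, double coul_kT,
                          bool only_boundary) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((long)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool bnd = (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1);
        if (only_boundary && !bnd) continue;
        double x = origin[0] + i * h, y = origin[1] + j * h, z = origin[2] + k * h;
        double v = 0.0;
        for (int t = 0; t < chg_xyz.nrow(); ++t) {
          double dx = x - chg_xyz(t, 0), dy = y - chg_xyz(t, 1), dz = z - chg_xyz(t, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < h / 2.0) r = h / 2.0;
          v += coul_kT * chg_q[t] * std::exp(-kappa * r) / (eps * r);
        }
        out[(long)i + (long)nx * ((long)j + (long)ny * (long)k)] = v;
      }
  return out;
}

// Trilinear interpolation of a grid field at arbitrary points (NA outside).
// [[Rcpp::export]]
NumericVector grid_interp_cpp(NumericVector phi, IntegerVector dims,
                              NumericVector origin, double h, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(pts.nrow());
  for (int t = 0; t < pts.nrow(); ++t) {
    double gx = (pts(t, 0) - origin[0]) / h;
    double gy = (pts(t, 1) - origin[1]) / h;
    double gz = (pts(t, 2) - origin[2]) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 || k0 >= nz - 1) {
      out[t] = NA_REAL; continue;
    }
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double v = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          v += w * phi[(long)(i0 + di) + (long)nx * ((long)(j0 + dj) + (long)ny * (long)(k0 + dk))];
        }
    out[t] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Titration engines
// ---------------------------------------------------------------------------

// Exact Boltzmann enumeration over 2^N protonation microstates.
// pka: intrinsic pKas; s: ionized-form charge sign (+1/-1); W: kcal/mol.
// Returns nPH x N matrix of mean ionization probability.
// [[Rcpp::export]]
NumericMatrix titr_exact_cpp(NumericVector pka, IntegerVector s, NumericMatrix W,
                             NumericVector ph_grid, double kT) {
  int N = pka.size();
  if (N > 20) stop("exact enumeration limited to 20 sites");
  long nstate = 1L << N;
  double ln10kT = std::log(10.0) * kT;
  // per-state: a = sum_ion s_i (pH coefficient), b = rest
  std::vector<double> A(nstate), B(nstate);
  for (long x = 0; x < nstate; ++x) {
    double a = 0.0, b = 0.0;
    for (int i = 0; i < N; ++i) {
      if (!(x >> i & 1)) continue;
      a += s[i];
      b -= s[i] * pka[i] * ln10kT;
      // W already carries the signed fully-ionized charges
      for (int j = i + 1; j < N; ++j)
        if (x >> j & 1) b += W(i, j);
    }
    A[x] = a * ln10kT; B[x] = b;
  }
  int nph = ph_grid.size();
  NumericMatrix out(nph, N);
  std::vector<double> snum(N);
  for (int p = 0; p < nph; ++p) {
    double ph = ph_grid[p];
    double emin = R_PosInf;
    for (long x = 0; x < nstate; ++x) {
      double e = A[x] * ph + B[x];
      if (e < emin) emin = e;
    }
    double Z = 0.0;
    std::fill(snum.begin(), snum.end(), 0.0);
    for (long x = 0; x < nstate; ++x) {
      double w = std::exp(-((A[x] * ph + B[x]) - emin) / kT);
      Z += w;
      long xx = x;
      while (xx) {
        int i = __builtin_ctzl(xx);
        snum[i] += w;
        xx &= xx - 1;
      }
    }
    for (int i = 0; i < N; ++i) out(p, i) = snum[i] / Z;
  }
  return out;
}

static inline double flip_dE(int i, const std::vector<int> &ion,
                             const NumericVector &pka, const IntegerVector &s,
                             const NumericMatrix &W, double ph, double ln10kT) {
  int N = pka.size();
  double d = (ion[i] ? -1.0 : 1.0);
  double e = s[i] * ln10kT * (ph - pka[i]);
  for (int j = 0; j < N; ++j)
    if (j != i && ion[j]) e += W(i, j);
  return d * e;
}

// Metropolis Monte Carlo titration; uses R's RNG (seed via set.seed()).
// Returns list(ion = nPH x N means, se = nPH x N batch-mean standard errors).
// [[Rcpp::export]]
List titr_mc_kt_cpp(NumericVector pka, IntegerVector s, NumericMatrix W,
                    NumericVector ph_grid, int n_equil, int n_sample,
                    double pair_threshold, double kT) {
  int N = pka.size();
  int nph = ph_grid.size();
  double ln10kT = std::log(10.0) * kT;
  // strongly coupled pairs
  std::vector<std::pair<int,int> > pairs;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (std::fabs(W(i, j)) > pair_threshold) pairs.push_back(std::make_pair(i, j));
  NumericMatrix mean_ion(nph, N), se_ion(nph, N);
  std::vector<int> ion(N);
  // initial state: Henderson-Hasselbalch guess at first pH
  for (int i = 0; i < N; ++i) {
    double ph0 = ph_grid[0];
    ion[i] = (s[i] < 0) ? (ph0 > pka[i]) : (ph0 < pka[i]);
  }
  // long batches keep the batch-mean standard error honest under the
  // autocorrelation of single-flip Metropolis sampling
  const int nbatch = 10;
  std::vector<double> acc(N), bsum(N), bsq(N), bacc(N);
  for (int p = 0; p < nph; ++p) {
    double ph = ph_grid[p];
    int ntot = n_equil + n_sample;
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(bsum.begin(), bsum.end(), 0.0);
    std::fill(bsq.begin(), bsq.end(), 0.0);
    std::fill(bacc.begin(), bacc.end(), 0.0);
    int batch_len = std::max(1, n_sample / nbatch);
    int bcount = 0, in_batch = 0;
    for (int t = 0; t < ntot; ++t) {
      bool pair_move = (!pairs.empty() && unif_rand() < 0.2);
      if (pair_move) {
        int pi = (int)(unif_rand() * pairs.size());
        if (pi >= (int)pairs.size()) pi = pairs.size() - 1;
        int i = pairs[pi].first, j = pairs[pi].second;
        double dE = flip_dE(i, ion, pka, s, W, ph, ln10kT);
        ion[i] = 1 - ion[i];
        dE += flip_dE(j, ion, pka, s, W, ph, ln10kT);
        ion[j] = 1 - ion[j];
        if (dE > 0 && unif_rand() >= std::exp(-dE / kT)) { // reject
          ion[i] = 1 - ion[i]; ion[j] = 1 - ion[j];
        }
      } else {
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        double dE = flip_dE(i, ion, pka, s, W, ph, ln10kT);
        if (dE <= 0 || unif_rand() < std::exp(-dE / kT)) ion[i] = 1 - ion[i];
      }
      if (t >= n_equil) {
        for (int i = 0; i < N; ++i) { acc[i] += ion[i]; bacc[i] += ion[i]; }
        if (++in_batch == batch_len) {
          for (int i = 0; i < N; ++i) {
            double bm = bacc[i] / batch_len;
            bsum[i] += bm; bsq[i] += bm * bm; bacc[i] = 0.0;
          }
          in_batch = 0; ++bcount;
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      mean_ion(p, i) = acc[i] / n_sample;
      if (bcount > 1) {
        double m = bsum[i] / bcount;
        double var = (bsq[i] / bcount - m * m) / (bcount - 1);
        se_ion(p, i) = std::sqrt(std::max(0.0, var));
      } else se_ion(p, i) = NA_REAL;
    }
  }
  return List::create(_["ion"] = mean_ion, _["se"] = se_ion);
}
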