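#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid transform: rotate about `centroid` by ZYX Euler angles, then shift.
// pose = (tx, ty, tz, rx, ry, rz); R = Rz(rz) * Ry(ry) * Rx(rx).
static void rotation_zyx(double rx, double ry, double rz, double R[9]) {
  const double cx = std::cos(rx), sx = std::sin(rx);
  const double cy = std::cos(ry), sy = std::sin(ry);
  const double cz = std::cos(rz), sz = std::sin(rz);
  R[0] = cz * cy;
  R[1] = cz * sy * sx - sz * cx;
  R[2] = cz * sy * cx + sz * sx;
  R[3] = sz * cy;
  R[4] = sz * sy * sx + cz * cx;
  R[5] = sz * sy * cx - cz * sx;
  R[6] = -sy;
  R[7] = cy * sx;
  R[8] = cy * cx;
}

static void transform_into(const double* x, const double* y, const double* z,
                           int m, const double* pose, const double* cen,
                           double* ox, double* oy, double* oz) {
  double R[9];
  rotation_zyx(pose[3], pose[4], pose[5], R);
  for (int i = 0; i < m; ++i) {
    const double dx = x[i] - cen[0];
    const double dy = y[i] - cen[1];
    const double dz = z[i] - cen[2];
    ox[i] = R[0] * dx + R[1] * dy + R[2] * dz + cen[0] + pose[0];
    oy[i] = R[3] * dx + R[4] * dy + R[5] * dz + cen[1] + pose[1];
    oz[i] = R[6] * dx + R[7] * dy + R[8] * dz + cen[2] + pose[2];
  }
}

// [[Rcpp::export]]
NumericMatrix transform_atoms_cpp(NumericMatrix xyz, NumericVector pose,
                                  NumericVector centroid) {
  const int m = xyz.nrow();
  NumericMatrix out(m, 3);
  std::vector<double> x(m), y(m), z(m), ox(m), oy(m), oz(m);
  for (int i = 0; i < m; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  transform_into(x.data(), y.data(), z.data(), m, pose.begin(),
                 centroid.begin(), ox.data(), oy.data(), oz.data());
  for (int i = 0; i < m; ++i) {
    out(i, 0) = ox[i]; out(i, 1) = oy[i]; out(i, 2) = oz[i];
  }
  return out;
}

// Smallest positive root of |o + t*u - c|^2 = r^2 over all atoms;
// tangency (zero discriminant) counts as a hit. Returns -1 when no hit.
static double first_hit(double ux, double uy, double uz,
                        const double* ax, const double* ay, const double* az,
                        const double* ar, int m,
                        double ox, double oy, double oz) {
  double best = -1.0;
  for (int i = 0; i < m; ++i) {
    const double mx = ax[i] - ox;
    const double my = ay[i] - oy;
    const double mz = az[i] - oz;
    const double b = ux * mx + uy * my + uz * mz;
    const double mm = mx * mx + my * my + mz * mz;
    const double disc = b * b - (mm - ar[i] * ar[i]);
    if (disc < 0.0) continue;
    const double s = std::sqrt(disc);
    double t = b - s;
    if (t <= 0.0) t = b + s;
    if (t > 0.0 && (best < 0.0 || t < best)) best = t;
  }
  return best;
}

struct ScoreAcc {
  double sum_unpack = 0.0;
  double sum_clash = 0.0;
  int n_miss = 0;
  int n_forbidden_hit = 0;
};

// Contribution of one ray given first-hit distance d (<0 means no hit).
// Returns the per-ray value; accumulates breakdown sums/counts.
static double ray_value(bool forbidden, double rho, double d,
                        const double* w, ScoreAcc& acc) {
  if (!forbidden) {
    if (d < 0.0) { acc.n_miss += 1; return w[2]; }
    if (d >= rho) { const double v = w[0] * (d - rho); acc.sum_unpack += v; return v; }
    const double v = w[1] * (rho - d);
    acc.sum_clash += v;
    return v;
  }
  if (d < 0.0) return 0.0;  // forbidden miss: does not contribute
  acc.n_forbidden_hit += 1;
  return w[3];
}

// Score one set of posed atoms against all rays.
// dirs: n x 3 unit vectors; keep[i]=false means the ray was eliminated and
// is treated as a guaranteed miss.
// [[Rcpp::export]]
List score_rays_cpp(NumericMatrix dirs, NumericVector rho,
                    LogicalVector forbidden, LogicalVector keep,
                    NumericMatrix atoms, NumericVector radii,
                    NumericVector origin, NumericVector w) {
  const int n = dirs.nrow();
  const int m = atoms.nrow();
  std::vector<double> ax(m), ay(m), az(m);
  for (int i = 0; i < m; ++i) {
    ax[i] = atoms(i, 0); ay[i] = atoms(i, 1); az[i] = atoms(i, 2);
  }
  const double* ar = radii.begin();
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  ScoreAcc acc;
  int n_pocket = 0;
  NumericVector values(n);
  NumericVector dists(n);
  for (int i = 0; i < n; ++i) {
    const bool forb = forbidden[i];
    if (!forb) ++n_pocket;
    double d = -1.0;
    if (m > 0 && keep[i]) {
      d = first_hit(dirs(i, 0), dirs(i, 1), dirs(i, 2),
                    ax.data(), ay.data(), az.data(), ar, m, ox, oy, oz);
    }
    values[i] = ray_value(forb, rho[i], d, w.begin(), acc);
    dists[i] = d < 0.0 ? NA_REAL : d;
  }
  const int n_contrib = n_pocket + acc.n_forbidden_hit;
  const double sum_miss = acc.n_miss * w[2];
  const double sum_forb = acc.n_forbidden_hit * w[3];
  const double total =
      (acc.sum_unpack + acc.sum_clash + sum_miss + sum_forb) / n_contrib;
  return List::create(
      _["total"] = total, _["sum_unpack"] = acc.sum_unpack,
      _["sum_clash"] = acc.sum_clash, _["sum_miss"] = sum_miss,
      _["sum_forbidden"] = sum_forb, _["n_miss"] = acc.n_miss,
      _["n_forbidden_hit"] = acc.n_forbidden_hit,
      _["n_contributing"] = n_contrib, _["values"] = values,
      _["distances"] = dists);
}

// Two-stage batch scorer: stage 1 fills the ray x pose contribution table,
// stage 2 reduces each pose (column) to a normalized total. No elimination,
// mirroring the branch-free batch design. Shares transform_into/first_hit/
// ray_value with the single-pose path so totals are bitwise identical.
// [[Rcpp::export]]
List score_swarm_cpp(NumericMatrix dirs, NumericVector rho,
                     LogicalVector forbidden, NumericMatrix atoms,
                     NumericVector radii, NumericVector centroid,
                     NumericMatrix poses, NumericVector origin,
                     NumericVector w, bool return_table) {
  const int n = dirs.nrow();
  const int m = atoms.nrow();
  const int k = poses.nrow();
  std::vector<double> bx(m), by(m), bz(m), ax(m), ay(m), az(m);
  for (int i = 0; i < m; ++i) {
    bx[i] = atoms(i, 0); by[i] = atoms(i, 1); bz[i] = atoms(i, 2);
  }
  const double* ar = radii.begin();
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  int n_pocket = 0;
  for (int i = 0; i < n; ++i)
    if (!forbidden[i]) ++n_pocket;

  NumericMatrix table = return_table ? NumericMatrix(n, k) : NumericMatrix(0, 0);
  NumericVector totals(k);
  std::vector<double> pose(6);
  for (int p = 0; p < k; ++p) {
    for (int j = 0; j < 6; ++j) pose[j] = poses(p, j);
    transform_into(bx.data(), by.data(), bz.data(), m, pose.data(),
                   centroid.begin(), ax.data(), ay.data(), az.data());
    ScoreAcc acc;
    for (int i = 0; i < n; ++i) {
      double d = -1.0;
      if (m > 0) {
        d = first_hit(dirs(i, 0), dirs(i, 1), dirs(i, 2),
                      ax.data(), ay.data(), az.data(), ar, m, ox, oy, oz);
      }
      const double v = ray_value(forbidden[i], rho[i], d, w.begin(), acc);
      if (return_table) table(i, p) = v;
    }
    const int n_contrib = n_pocket + acc.n_forbidden_hit;
    totals[p] = (acc.sum_unpack + acc.sum_clash + acc.n_miss * w[2] +
                 acc.n_forbidden_hit * w[3]) /
                n_contrib;
  }
  return List::create(_["totals"] = totals,
                      _["table"] = return_table ? (SEXP)table : R_NilValue);
}

// Label grid points P (1) when within (<=) any atom's radius of its center.
// labels codes: 0 = S, 1 = P, 2 = pocket (PSP), 3 = shell, 4 = forbidden.
// [[Rcpp::export]]
IntegerVector classify_grid_cpp(IntegerVector labels, IntegerVector dims,
                                NumericVector lower, double spacing,
                                NumericMatrix atoms, NumericVector radii) {
  IntegerVector lab = clone(labels);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  for (int a = 0; a < atoms.nrow(); ++a) {
    const double cx = atoms(a, 0), cy = atoms(a, 1), cz = atoms(a, 2);
    const double r = radii[a];
    const double r2 = r * r;
    int i0 = (int)std::ceil((cx - r - lower[0]) / spacing);
    int i1 = (int)std::floor((cx + r - lower[0]) / spacing);
    int j0 = (int)std::ceil((cy - r - lower[1]) / spacing);
    int j1 = (int)std::floor((cy + r - lower[1]) / spacing);
    int k0 = (int)std::ceil((cz - r - lower[2]) / spacing);
    int k1 = (int)std::floor((cz + r - lower[2]) / spacing);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = lower[2] + k * spacing - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = lower[1] + j * spacing - cy;
        for (int i = i0; i <= i1; ++i) {
          const double dx = lower[0] + i * spacing - cx;
          if (dx * dx + dy * dy + dz * dz <= r2)
            lab[i + nx * (j + (R_xlen_t)ny * k)] = 1;
        }
      }
    }
  }
  return lab;
}

// Protein-solvent-protein pocket marking: an S point becomes pocket (2) when
// along one of 7 scan directions (3 axes + 4 body diagonals) a P point lies
// within max_span steps on each side, with only S/pocket points between
// (automatic: the walk stops at the first P).
// [[Rcpp::export]]
IntegerVector mark_pocket_cpp(IntegerVector labels, IntegerVector dims,
                              int max_span) {
  IntegerVector lab = clone(labels);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dirs[7][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 1},
                          {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + nx * (j + (R_xlen_t)ny * k);
        if (labels[idx] != 0) continue;
        bool pocket = false;
        for (int d = 0; d < 7 && !pocket; ++d) {
          bool ok_pos = false, ok_neg = false;
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            const int di = sgn * dirs[d][0];
            const int dj = sgn * dirs[d][1];
            const int dk = sgn * dirs[d][2];
            int ci = i, cj = j, ck = k;
            for (int s = 1; s <= max_span; ++s) {
              ci += di; cj += dj; ck += dk;
              if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 ||
                  ck >= nz)
                break;
              if (labels[ci + nx * (cj + (R_xlen_t)ny * ck)] == 1) {
                if (sgn > 0) ok_pos = true; else ok_neg = true;
                break;
              }
            }
          }
          pocket = ok_pos && ok_neg;
        }
        if (pocket) lab[idx] = 2;
      }
    }
  }
  return lab;
}

// TRUE for each point whose distance to the nearest reference point is
// within cutoff (early-exit brute force).
// [[Rcpp::export]]
LogicalVector min_dist_filter_cpp(NumericMatrix pts, NumericMatrix ref,
                                  double cutoff) {
  const int n = pts.nrow(), m = ref.nrow();
  const double c2 = cutoff * cutoff;
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool hit = false;
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int j = 0; j < m && !hit; ++j) {
      const double dx = x - ref(j, 0);
      const double dy = y - ref(j, 1);
      const double dz = z - ref(j, 2);
      hit = dx * dx + dy * dy + dz * dz <= c2;
    }
    out[i] = hit;
  }
  return out;
}
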