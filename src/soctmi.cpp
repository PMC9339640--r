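#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Siddon-style exact radiological path through a voxel grid.
// Returns sum of density * intersection length, in g/cm^2 (lengths in mm
// are converted by 0.1). Grid origin is the world position of the center of
// voxel (0,0,0).
// ---------------------------------------------------------------------------

static double ray_path(const double* dens, const int* dims,
                       const double* sp, const double* org,
                       const double* p0, const double* p1) {
  double d[3], lo[3], hi[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    L2 += d[a] * d[a];
    lo[a] = org[a] - 0.5 * sp[a];
    hi[a] = lo[a] + dims[a] * sp[a];
  }
  double L = std::sqrt(L2);
  if (L == 0.0) return 0.0;

  // clip the segment parameter t in [0,1] to the grid bounding box
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (d[a] == 0.0) {
      if (p0[a] <= lo[a] || p0[a] >= hi[a]) return 0.0;
    } else {
      double t0 = (lo[a] - p0[a]) / d[a];
      double t1 = (hi[a] - p0[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmin >= tmax) return 0.0;

  // entry voxel
  int idx[3], step[3];
  double tnext[3], tdelta[3];
  const double inf = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    double pa = p0[a] + (tmin + 1e-12) * d[a];
    int i = (int)std::floor((pa - lo[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i >= dims[a]) i = dims[a] - 1;
    idx[a] = i;
    if (d[a] > 0.0) {
      step[a] = 1;
      tdelta[a] = sp[a] / d[a];
      tnext[a] = (lo[a] + (i + 1) * sp[a] - p0[a]) / d[a];
    } else if (d[a] < 0.0) {
      step[a] = -1;
      tdelta[a] = -sp[a] / d[a];
      tnext[a] = (lo[a] + i * sp[a] - p0[a]) / d[a];
    } else {
      step[a] = 0;
      tdelta[a] = inf;
      tnext[a] = inf;
    }
  }

  double sum = 0.0, tcur = tmin;
  while (tcur < tmax) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tstop = tnext[ax] < tmax ? tnext[ax] : tmax;
    double len = (tstop - tcur) * L;
    if (len > 0.0) {
      R_xlen_t lin = (R_xlen_t)idx[0] +
        (R_xlen_t)dims[0] * ((R_xlen_t)idx[1] + (R_xlen_t)dims[1] * idx[2]);
      sum += dens[lin] * len;
    }
    tcur = tstop;
    if (tnext[ax] >= tmax) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= dims[ax]) break;
    tnext[ax] += tdelta[ax];
  }
  return sum * 0.1;  // mm * g/cm^3 -> g/cm^2
}

// [[Rcpp::export]]
double cpp_radiological_path(NumericVector density, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector p0, NumericVector p1) {
  return ray_path(REAL(density), INTEGER(dims), REAL(spacing), REAL(origin),
                  REAL(p0), REAL(p1));
}

// ---------------------------------------------------------------------------
// Beamlet dose model. For a voxel at world point v and a field with source
// S, isocenter axis w (unit, source -> isocenter), in-plane basis e1,e2 and
// source-isocenter distance SID:
//   s      = (v - S) . w                       (depth along the field axis)
//   (x, y) = back-projection of v onto the isocenter plane along the ray
//   dose   = calib * (SID/s)^2 * exp(-mu * d_rad(v)) * f_medium(v)
//            * (b^2 / (2 pi sigma^2)) * exp(-r^2 / (2 sigma^2))
// where r is the isocenter-plane distance to the beamlet center and d_rad
// the exact radiological path from the source to the voxel center.
// ---------------------------------------------------------------------------

struct FieldGeom {
  double S[3], iso[3], w[3], e1[3], e2[3];
  double sid, b, x0, y0;
  int n1, n2;
};

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export]]
List cpp_influence_field(NumericVector density, IntegerVector dims,
                         NumericVector spacing, NumericVector origin,
                         IntegerVector support, IntegerVector materials,
                         NumericVector enh_factor,
                         NumericVector src, NumericVector iso,
                         NumericVector e1, NumericVector e2,
                         double sid, int n1, int n2, double b,
                         double x0, double y0,
                         double mu, double sigma, double cutoff,
                         double calib) {
  const double* dens = REAL(density);
  const int* dm = INTEGER(dims);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  const double* S = REAL(src);
  double w[3];
  double nw = 0.0;
  for (int a = 0; a < 3; ++a) { w[a] = iso[a] - S[a]; nw += w[a] * w[a]; }
  nw = std::sqrt(nw);
  for (int a = 0; a < 3; ++a) w[a] /= nw;

  double sig2 = sigma * sigma;
  double knorm = b * b / (2.0 * M_PI * sig2);
  double cut2 = cutoff * cutoff;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(support.size() * 8);
  tj.reserve(support.size() * 8);
  tx.reserve(support.size() * 8);

  for (R_xlen_t k = 0; k < support.size(); ++k) {
    R_xlen_t lin = support[k];
    int i0 = (int)(lin % dm[0]);
    int j0 = (int)((lin / dm[0]) % dm[1]);
    int k0 = (int)(lin / ((R_xlen_t)dm[0] * dm[1]));
    double v[3] = { org[0] + i0 * sp[0], org[1] + j0 * sp[1], org[2] + k0 * sp[2] };
    double rel[3] = { v[0] - S[0], v[1] - S[1], v[2] - S[2] };
    double s = dot3(rel, w);
    if (s < 1e-6) continue;
    double scale = sid / s;
    double q[3];
    for (int a = 0; a < 3; ++a) q[a] = S[a] + rel[a] * scale - iso[a];
    double x = dot3(q, REAL(e1));
    double y = dot3(q, REAL(e2));
    int ilo = (int)std::ceil((x - cutoff - x0) / b);
    int ihi = (int)std::floor((x + cutoff - x0) / b);
    int jlo = (int)std::ceil((y - cutoff - y0) / b);
    int jhi = (int)std::floor((y + cutoff - y0) / b);
    if (ilo < 0) ilo = 0;
    if (jlo < 0) jlo = 0;
    if (ihi >= n1) ihi = n1 - 1;
    if (jhi >= n2) jhi = n2 - 1;
    if (ilo > ihi || jlo > jhi) continue;
    double drad = ray_path(dens, dm, sp, org, S, v);
    double base = calib * scale * scale * std::exp(-mu * drad) *
      enh_factor[materials[lin]] * knorm;
    for (int bi = ilo; bi <= ihi; ++bi) {
      double dx = x - (x0 + bi * b);
      for (int bj = jlo; bj <= jhi; ++bj) {
        double dy = y - (y0 + bj * b);
        double r2 = dx * dx + dy * dy;
        if (r2 > cut2) continue;
        double val = base * std::exp(-r2 / (2.0 * sig2));
        ti.push_back((int)k);
        tj.push_back(bj * n1 + bi);  // column-major over (n1, n2) map
        tx.push_back(val);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// Forward dose of a fixed field: unit weight on every open beamlet.
// `aperture` is a logical vector over the (n1, n2) beamlet lattice in
// column-major layout (index bj*n1 + bi).
// [[Rcpp::export]]
NumericVector cpp_fixed_field_dose(NumericVector density, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   IntegerVector materials,
                                   NumericVector enh_factor,
                                   LogicalVector aperture,
                                   NumericVector src, NumericVector iso,
                                   NumericVector e1, NumericVector e2,
                                   double sid, int n1, int n2, double b,
                                   double x0, double y0,
                                   double mu, double sigma, double cutoff,
                                   double calib) {
  const double* dens = REAL(density);
  const int* dm = INTEGER(dims);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  const double* S = REAL(src);
  double w[3];
  double nw = 0.0;
  for (int a = 0; a < 3; ++a) { w[a] = iso[a] - S[a]; nw += w[a] * w[a]; }
  nw = std::sqrt(nw);
  for (int a = 0; a < 3; ++a) w[a] /= nw;
  double sig2 = sigma * sigma;
  double knorm = b * b / (2.0 * M_PI * sig2);
  double cut2 = cutoff * cutoff;

  R_xlen_t N = (R_xlen_t)dm[0] * dm[1] * dm[2];
  NumericVector dose(N);
  for (R_xlen_t lin = 0; lin < N; ++lin) {
    int i0 = (int)(lin % dm[0]);
    int j0 = (int)((lin / dm[0]) % dm[1]);
    int k0 = (int)(lin / ((R_xlen_t)dm[0] * dm[1]));
    double v[3] = { org[0] + i0 * sp[0], org[1] + j0 * sp[1], org[2] + k0 * sp[2] };
    double rel[3] = { v[0] - S[0], v[1] - S[1], v[2] - S[2] };
    double s = dot3(rel, w);
    if (s < 1e-6) continue;
    double scale = sid / s;
    double q[3];
    for (int a = 0; a < 3; ++a) q[a] = S[a] + rel[a] * scale - iso[a];
    double x = dot3(q, REAL(e1));
    double y = dot3(q, REAL(e2));
    int ilo = (int)std::ceil((x - cutoff - x0) / b);
    int ihi = (int)std::floor((x + cutoff - x0) / b);
    int jlo = (int)std::ceil((y - cutoff - y0) / b);
    int jhi = (int)std::floor((y + cutoff - y0) / b);
    if (ilo < 0) ilo = 0;
    if (jlo < 0) jlo = 0;
    if (ihi >= n1) ihi = n1 - 1;
    if (jhi >= n2) jhi = n2 - 1;
    if (ilo > ihi || jlo > jhi) continue;
    double ksum = 0.0;
    for (int bi = ilo; bi <= ihi; ++bi) {
      double dx = x - (x0 + bi * b);
      for (int bj = jlo; bj <= jhi; ++bj) {
        if (!aperture[(R_xlen_t)bj * n1 + bi]) continue;
        double dy = y - (y0 + bj * b);
        double r2 = dx * dx + dy * dy;
        if (r2 > cut2) continue;
        ksum += std::exp(-r2 / (2.0 * sig2));
      }
    }
    if (ksum == 0.0) continue;
    double drad = ray_path(dens, dm, sp, org, S, v);
    dose[lin] = calib * scale * scale * std::exp(-mu * drad) *
      enh_factor[materials[lin]] * knorm * ksum;
  }
  return dose;
}

// ---------------------------------------------------------------------------
// 1-D total-variation proximal operator (Condat's direct algorithm):
//   argmin_x 0.5 ||x - y||^2 + lam * sum |x_{i+1} - x_i|
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tv1d(NumericVector y, double lam) {
  int N = y.size();
  NumericVector x(N);
  if (N == 0) return x;
  if (N == 1 || lam <= 0.0) { for (int i = 0; i < N; ++i) x[i] = y[i]; return x; }

  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lam, vmax = y[0] + lam;
  double umin = lam, umax = -lam;

  for (;;) {
    if (k == N - 1) {
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = km + 1;
        vmin = y[k];
        umin = lam;
        umax = y[k] + lam - vmax;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = kp = kp + 1;
        vmax = y[k];
        umax = -lam;
        umin = y[k] - lam - vmin;
      } else {
        double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i <= N - 1; ++i) x[i] = v;
        return x;
      }
      if (k == N - 1) {  // re-check termination on the final element
        // fall through: loop will handle via the same branch structure
      }
      continue;
    }
    double yk1 = y[k + 1];
    if (yk1 + umin < vmin - lam) {            // negative jump necessary
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k = k0 = km = kp = km + 1;
      vmin = y[k];
      vmax = y[k] + 2.0 * lam;
      umin = lam;
      umax = -lam;
    } else if (yk1 + umax > vmax + lam) {     // positive jump necessary
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k = k0 = km = kp = kp + 1;
      vmin = y[k] - 2.0 * lam;
      vmax = y[k];
      umin = lam;
      umax = -lam;
    } else {                                   // no jump: extend the segment
      k = k + 1;
      umin += yk1 - vmin;
      umax += yk1 - vmax;
      if (umin >= lam) {
        vmin += (umin - lam) / (k - k0 + 1);
        umin = lam;
        km = k;
      }
      if (umax <= -lam) {
        vmax += (umax + lam) / (k - k0 + 1);
        umax = -lam;
        kp = k;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Greedy rectangle peeling of a nonnegative fluence map.
// At each step choose the axis-aligned rectangle maximizing
// (min residual over the rectangle) * area, i.e. the largest possible L1
// reduction with a weight that keeps the residual nonnegative. Ties prefer
// the larger area, then the smallest (r0, c0) in row-major order, then the
// smallest (r1, c1).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_peel_rectangles(NumericMatrix M, double tol, int budget) {
  int R = M.nrow(), C = M.ncol();
  NumericMatrix res = clone(M);
  double total = 0.0;
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j) total += res(i, j);
  double target = tol * total;
  double remaining = total;

  std::vector<int> vr0, vr1, vc0, vc1;
  std::vector<double> vw;
  std::vector<double> colmin(C);
  const double eps = 1e-12 * (total > 0 ? total : 1.0);

  while (remaining > target && (int)vw.size() < budget) {
    double best = 0.0;
    int br0 = -1, br1 = -1, bc0 = -1, bc1 = -1, barea = 0;
    double bw = 0.0;
    for (int r0 = 0; r0 < R; ++r0) {
      for (int j = 0; j < C; ++j) colmin[j] = std::numeric_limits<double>::infinity();
      for (int r1 = r0; r1 < R; ++r1) {
        for (int j = 0; j < C; ++j) {
          double v = res(r1, j);
          if (v < colmin[j]) colmin[j] = v;
        }
        int rows = r1 - r0 + 1;
        for (int c0 = 0; c0 < C; ++c0) {
          double m = std::numeric_limits<double>::infinity();
          for (int c1 = c0; c1 < C; ++c1) {
            if (colmin[c1] < m) m = colmin[c1];
            if (m <= 0.0) break;
            int area = rows * (c1 - c0 + 1);
            double red = m * area;
            bool take = false;
            if (red > best + eps) take = true;
            else if (red > best - eps) {
              if (area > barea) take = true;
              else if (area == barea) {
                if (r0 < br0 || (r0 == br0 && (c0 < bc0 ||
                    (c0 == bc0 && (r1 < br1 || (r1 == br1 && c1 < bc1)))))) {
                  take = true;
                }
              }
            }
            if (take) {
              best = red; barea = area; bw = m;
              br0 = r0; br1 = r1; bc0 = c0; bc1 = c1;
            }
          }
        }
      }
    }
    if (br0 < 0 || best <= eps) break;
    for (int i = br0; i <= br1; ++i)
      for (int j = bc0; j <= bc1; ++j) res(i, j) -= bw;
    remaining -= best;
    vr0.push_back(br0); vr1.push_back(br1);
    vc0.push_back(bc0); vc1.push_back(bc1);
    vw.push_back(bw);
  }

  // recompute the residual L1 exactly (guards against drift)
  double l1 = 0.0;
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j) l1 += std::fabs(res(i, j));

  return List::create(
    _["r0"] = wrap(vr0), _["r1"] = wrap(vr1),
    _["c0"] = wrap(vc0), _["c1"] = wrap(vc1),
    _["weight"] = wrap(vw),
    _["residual_l1"] = l1,
    _["map_l1"] = total);
}

// ---------------------------------------------------------------------------
// Connected components of a 3-D logical array under 26-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(N, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < N; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++cur;
    stack.push_back(start);
    labels[start] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            if (!di && !dj && !dk) continue;
            R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
            if (mask[q] && !labels[q]) { labels[q] = cur; stack.push_back(q); }
          }
        }
      }
    }
  }
  return labels;
}
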