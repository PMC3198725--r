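#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Reflect an index into [0, n) (symmetric boundary, edge repeated:
// ... c b a | a b c ... | c b a ...). Handles offsets larger than n.
static inline int reflect_index(int p, int n) {
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -1 - p;
    else       p = 2 * n - 1 - p;
  }
  return p;
}

// Correlate a 3D array (column-major, dim = d0 x d1 x d2) with a 1D
// kernel along one axis, reflective boundary. kernel[t] weights offset
// t - (L-1)/2; L must be odd. Axis 0 runs a stencil over contiguous
// lines; axes 1 and 2 accumulate whole contiguous slabs per kernel tap
// so memory is streamed, never strided.
// [[Rcpp::export]]
NumericVector conv3d_axis(NumericVector x, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const int L = kernel.size();
  if (L % 2 == 0) stop("kernel length must be odd");
  const int h = (L - 1) / 2;
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");

  NumericVector out(x.size());
  const double *k = kernel.begin();
  const double *in = x.begin();
  double *op = out.begin();

  if (axis == 0) {
    const R_xlen_t nline = (R_xlen_t)d1 * d2;
    std::vector<double> buf(d0 + 2 * h);
    for (R_xlen_t l = 0; l < nline; ++l) {
      const double *p = in + l * d0;
      double *q = op + l * d0;
      for (int j = 0; j < d0; ++j) buf[j + h] = p[j];
      for (int j = 0; j < h; ++j) {
        buf[h - 1 - j] = p[reflect_index(-1 - j, d0)];
        buf[d0 + h + j] = p[reflect_index(d0 + j, d0)];
      }
      for (int j = 0; j < d0; ++j) {
        double s = 0.0;
        const double *b = &buf[j];
        for (int t = 0; t < L; ++t) s += k[t] * b[t];
        q[j] = s;
      }
    }
  } else if (axis == 1) {
    // per x-slab, accumulate columns: out[,y,x] += k[t] * in[,yy,x]
    const R_xlen_t slab = (R_xlen_t)d0 * d1;
    for (int xx = 0; xx < d2; ++xx) {
      const double *ps = in + (R_xlen_t)xx * slab;
      double *qs = op + (R_xlen_t)xx * slab;
      for (int y = 0; y < d1; ++y) {
        double *q = qs + (R_xlen_t)y * d0;
        for (int t = 0; t < L; ++t) {
          const double kt = k[t];
          if (kt == 0.0) continue;
          const double *p = ps + (R_xlen_t)reflect_index(y + t - h, d1) * d0;
          for (int j = 0; j < d0; ++j) q[j] += kt * p[j];
        }
      }
    }
  } else {
    // accumulate whole (d0*d1) slabs: out[,,x] += k[t] * in[,,xx]
    const R_xlen_t slab = (R_xlen_t)d0 * d1;
    for (int xx = 0; xx < d2; ++xx) {
      double *q = op + (R_xlen_t)xx * slab;
      for (int t = 0; t < L; ++t) {
        const double kt = k[t];
        if (kt == 0.0) continue;
        const double *p = in + (R_xlen_t)reflect_index(xx + t - h, d2) * slab;
        for (R_xlen_t j = 0; j < slab; ++j) q[j] += kt * p[j];
      }
    }
  }
  return out;
}

// Eigenvalues of symmetric 3x3 matrices, sorted descending by signed
// value. Inputs are the six unique components per matrix; output is an
// n x 3 matrix. Uses the trigonometric closed form.
// [[Rcpp::export]]
NumericMatrix eig3_sym_desc(NumericVector a11, NumericVector a22,
                            NumericVector a33, NumericVector a12,
                            NumericVector a13, NumericVector a23) {
  const R_xlen_t n = a11.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m11 = a11[i], m22 = a22[i], m33 = a33[i];
    const double m12 = a12[i], m13 = a13[i], m23 = a23[i];
    const double p1 = m12 * m12 + m13 * m13 + m23 * m23;
    double e1, e2, e3;
    if (p1 == 0.0) {
      e1 = m11; e2 = m22; e3 = m33;
    } else {
      const double q = (m11 + m22 + m33) / 3.0;
      const double b11 = m11 - q, b22 = m22 - q, b33 = m33 - q;
      const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // det(B)/2 where B = (A - qI)/p
      const double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
      const double c12 = m12 / p, c13 = m13 / p, c23 = m23 / p;
      double r = (c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r >  1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    // sort descending
    if (e1 < e2) std::swap(e1, e2);
    if (e2 < e3) std::swap(e2, e3);
    if (e1 < e2) std::swap(e1, e2);
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}

struct NeighborOffsets {
  std::vector<int> dz, dy, dx;
};

static NeighborOffsets make_offsets(int connectivity) {
  NeighborOffsets o;
  int maxsum;
  if (connectivity == 6) maxsum = 1;
  else if (connectivity == 18) maxsum = 2;
  else if (connectivity == 26) maxsum = 3;
  else stop("connectivity must be 6, 18 or 26");
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0 || s > maxsum) continue;
        o.dz.push_back(a); o.dy.push_back(b); o.dx.push_back(c);
      }
  return o;
}

// Label connected components of a logical mask (column-major z,y,x
// array). Labels are 1..n in scan order of each component's first
// voxel; 0 is background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t total = (R_xlen_t)d0 * d1 * d2;
  if ((R_xlen_t)mask.size() != total) stop("mask size does not match dim");
  NeighborOffsets off = make_offsets(connectivity);
  const int noff = (int)off.dz.size();
  IntegerVector lab(total, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int z = (int)(cur % d0);
      const int y = (int)((cur / d0) % d1);
      const int x = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int t = 0; t < noff; ++t) {
        const int zz = z + off.dz[t], yy = y + off.dy[t], xx = x + off.dx[t];
        if (zz < 0 || zz >= d0 || yy < 0 || yy >= d1 || xx < 0 || xx >= d2)
          continue;
        const R_xlen_t j = zz + (R_xlen_t)d0 * (yy + (R_xlen_t)d1 * xx);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Hysteresis growth: voxels with value >= relax (plus all core voxels)
// are eligible; each connected component of the eligible set that
// contains core voxels is assigned to those cores. Components holding
// a single core go wholly to it; in components holding several cores,
// non-core voxels are contested and go to the core with the nearest
// (Euclidean) core voxel, ties to the lower core id. Eligible
// components without any core are dropped.
// [[Rcpp::export]]
IntegerVector grow_segments_cpp(IntegerVector core_lab, NumericVector vals,
                                double relax, IntegerVector dim,
                                int connectivity) {
  const R_xlen_t total = core_lab.size();
  if (vals.size() != total) stop("size mismatch");
  LogicalVector eligible(total);
  for (R_xlen_t i = 0; i < total; ++i)
    eligible[i] = (vals[i] >= relax) || (core_lab[i] > 0);
  IntegerVector comp = label_components_cpp(eligible, dim, connectivity);

  int ncomp = 0, ncore = 0;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (comp[i] > ncomp) ncomp = comp[i];
    if (core_lab[i] > ncore) ncore = core_lab[i];
  }
  // which cores live in which component (core voxels keep their label)
  std::vector<int> comp_core(ncomp + 1, 0);      // 0 none, -1 multiple
  for (R_xlen_t i = 0; i < total; ++i) {
    const int c = comp[i], k = core_lab[i];
    if (k <= 0) continue;
    if (comp_core[c] == 0) comp_core[c] = k;
    else if (comp_core[c] != k) comp_core[c] = -1;
  }
  IntegerVector out(total, 0);
  bool any_multi = false;
  for (int c = 1; c <= ncomp; ++c) if (comp_core[c] == -1) any_multi = true;
  for (R_xlen_t i = 0; i < total; ++i) {
    const int c = comp[i];
    if (c == 0) continue;
    if (core_lab[i] > 0) out[i] = core_lab[i];
    else if (comp_core[c] > 0) out[i] = comp_core[c];
  }
  if (!any_multi) return out;

  const int d0 = dim[0], d1 = dim[1];
  // core voxel coordinate lists, restricted to multi-core components
  std::vector< std::vector<double> > cz(ncore + 1), cy(ncore + 1), cx(ncore + 1);
  for (R_xlen_t i = 0; i < total; ++i) {
    const int k = core_lab[i];
    if (k <= 0 || comp_core[comp[i]] != -1) continue;
    cz[k].push_back((double)(i % d0));
    cy[k].push_back((double)((i / d0) % d1));
    cx[k].push_back((double)(i / ((R_xlen_t)d0 * d1)));
  }
  // cores present per multi-core component
  std::vector< std::vector<int> > comp_cores(ncomp + 1);
  for (int k = 1; k <= ncore; ++k)
    if (!cz[k].empty()) {
      // find component of this core (any voxel)
      // record below during contested scan instead
      (void)0;
    }
  for (R_xlen_t i = 0; i < total; ++i) {
    const int k = core_lab[i];
    if (k <= 0 || comp_core[comp[i]] != -1) continue;
    std::vector<int> &v = comp_cores[comp[i]];
    if (std::find(v.begin(), v.end(), k) == v.end()) v.push_back(k);
  }
  for (int c = 1; c <= ncomp; ++c) std::sort(comp_cores[c].begin(), comp_cores[c].end());

  for (R_xlen_t i = 0; i < total; ++i) {
    const int c = comp[i];
    if (c == 0 || comp_core[c] != -1 || core_lab[i] > 0) continue;
    const double z = (double)(i % d0);
    const double y = (double)((i / d0) % d1);
    const double x = (double)(i / ((R_xlen_t)d0 * d1));
    double best = R_PosInf;
    int bestk = 0;
    for (size_t u = 0; u < comp_cores[c].size(); ++u) {
      const int k = comp_cores[c][u];
      const std::vector<double> &az = cz[k], &ay = cy[k], &ax = cx[k];
      double dmin = R_PosInf;
      for (size_t t = 0; t < az.size(); ++t) {
        const double dz = z - az[t], dy = y - ay[t], dx = x - ax[t];
        const double d = dz * dz + dy * dy + dx * dx;
        if (d < dmin) dmin = d;
      }
      if (dmin < best) { best = dmin; bestk = k; }  // ties keep lower id
    }
    out[i] = bestk;
  }
  return out;
}

// Distance (Euclidean, voxel units) to the nearest and second-nearest
// of a set of seed points, for every voxel of a (d0,d1,d2) grid.
// Seeds are an m x 3 matrix of 0-based (z,y,x). Used by the synthetic
// Voronoi membrane model.
// [[Rcpp::export]]
NumericMatrix voronoi_d12(IntegerVector dim, NumericMatrix seeds) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t total = (R_xlen_t)d0 * d1 * d2;
  const int m = seeds.nrow();
  NumericMatrix out(total, 2);
  R_xlen_t i = 0;
  for (int x = 0; x < d2; ++x)
    for (int y = 0; y < d1; ++y)
      for (int z = 0; z < d0; ++z, ++i) {
        double m1 = R_PosInf, m2 = R_PosInf;
        for (int s = 0; s < m; ++s) {
          const double dz = z - seeds(s, 0), dy = y - seeds(s, 1),
                       dx = x - seeds(s, 2);
          const double d = dz * dz + dy * dy + dx * dx;
          if (d < m1) { m2 = m1; m1 = d; }
          else if (d < m2) m2 = d;
        }
        out(i, 0) = std::sqrt(m1);
        out(i, 1) = std::sqrt(m2);
      }
  return out;
}
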