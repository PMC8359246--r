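#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are column-major 3D arrays. Physical coordinates are mm, with the
// centre of voxel (i, j, k) (1-based in R) at ((i-1)*s1, (j-1)*s2, (k-1)*s3).

static inline double trilerp(const NumericVector &vol, int n1, int n2, int n3,
                             double x, double y, double z, double oob) {
  // x, y, z in 0-based voxel units
  if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1)
    return oob;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == n1 - 1) i0--;
  if (j0 == n2 - 1) j0--;
  if (k0 == n3 - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double *v = vol.begin();
  size_t s2s = (size_t)n1, s3s = (size_t)n1 * n2;
  size_t b = (size_t)i0 + (size_t)j0 * s2s + (size_t)k0 * s3s;
  double c000 = v[b], c100 = v[b + 1];
  double c010 = v[b + s2s], c110 = v[b + 1 + s2s];
  double c001 = v[b + s3s], c101 = v[b + 1 + s3s];
  double c011 = v[b + s2s + s3s], c111 = v[b + 1 + s2s + s3s];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nnsample(const NumericVector &vol, int n1, int n2, int n3,
                              double x, double y, double z, double oob) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
      k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i > n1 - 1 || j > n2 - 1 || k > n3 - 1)
    return oob;
  return vol[(size_t)i + (size_t)j * n1 + (size_t)k * (size_t)n1 * n2];
}

// Resample vol at x -> A (x - c) + c + t (all mm); returns volume on same grid.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericMatrix A,
                                  NumericVector t, NumericVector centre,
                                  bool nearest, double oob) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((size_t)n1 * n2 * n3);
  double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  size_t idx = 0;
  for (int k = 0; k < n3; k++) {
    double zm = k * s3 - centre[2];
    for (int j = 0; j < n2; j++) {
      double ym = j * s2 - centre[1];
      for (int i = 0; i < n1; i++, idx++) {
        double xm = i * s1 - centre[0];
        double px = A(0, 0) * xm + A(0, 1) * ym + A(0, 2) * zm + centre[0] + t[0];
        double py = A(1, 0) * xm + A(1, 1) * ym + A(1, 2) * zm + centre[1] + t[1];
        double pz = A(2, 0) * xm + A(2, 1) * ym + A(2, 2) * zm + centre[2] + t[2];
        double vx = px / s1, vy = py / s2, vz = pz / s3;
        out[idx] = nearest ? nnsample(vol, n1, n2, n3, vx, vy, vz, oob)
                           : trilerp(vol, n1, n2, n3, vx, vy, vz, oob);
      }
    }
  }
  return out;
}

// Resample vol at x + u(x); disp is (n1*n2*n3 x 3) in mm on the same grid.
// [[Rcpp::export]]
NumericVector resample_field_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector disp,
                                 bool nearest, double oob) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  NumericVector out(n);
  double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double *ux = disp.begin(), *uy = ux + n, *uz = uy + n;
  size_t idx = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++, idx++) {
        double vx = (i * s1 + ux[idx]) / s1;
        double vy = (j * s2 + uy[idx]) / s2;
        double vz = (k * s3 + uz[idx]) / s3;
        out[idx] = nearest ? nnsample(vol, n1, n2, n3, vx, vy, vz, oob)
                           : trilerp(vol, n1, n2, n3, vx, vy, vz, oob);
      }
  return out;
}

// Trilinear sample of a scalar volume at arbitrary mm points (r x 3 matrix).
// [[Rcpp::export]]
NumericVector sample_points_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericMatrix pts,
                                double oob) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int r = pts.nrow();
  NumericVector out(r);
  for (int q = 0; q < r; q++)
    out[q] = trilerp(vol, n1, n2, n3, pts(q, 0) / spacing[0],
                     pts(q, 1) / spacing[1], pts(q, 2) / spacing[2], oob);
  return out;
}

// Resize a volume to new dims by trilinear interpolation (grid-aligned ends).
// [[Rcpp::export]]
NumericVector resize_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   IntegerVector newdim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int m1 = newdim[0], m2 = newdim[1], m3 = newdim[2];
  NumericVector out((size_t)m1 * m2 * m3);
  double f1 = m1 > 1 ? (double)(n1 - 1) / (m1 - 1) : 0.0;
  double f2 = m2 > 1 ? (double)(n2 - 1) / (m2 - 1) : 0.0;
  double f3 = m3 > 1 ? (double)(n3 - 1) / (m3 - 1) : 0.0;
  size_t idx = 0;
  for (int k = 0; k < m3; k++)
    for (int j = 0; j < m2; j++)
      for (int i = 0; i < m1; i++, idx++)
        out[idx] = trilerp(vol, n1, n2, n3, i * f1, j * f2, k * f3, 0.0);
  return out;
}

// Separable Gaussian smoothing; sigma per axis in voxel units, radius 3 sigma.
static void smooth_axis(std::vector<double> &v, int n1, int n2, int n3,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double &kv : kern) kv /= s;
  size_t strides[3] = {1, (size_t)n1, (size_t)n1 * n2};
  int dims[3] = {n1, n2, n3};
  size_t st = strides[axis];
  int len = dims[axis];
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(len);
  for (int b = 0; b < dims[o2]; b++)
    for (int a = 0; a < dims[o1]; a++) {
      size_t base = (size_t)a * strides[o1] + (size_t)b * strides[o2];
      for (int i = 0; i < len; i++) line[i] = v[base + (size_t)i * st];
      for (int i = 0; i < len; i++) {
        double acc = 0, wsum = 0;
        for (int q = -r; q <= r; q++) {
          int p = i + q;
          if (p < 0 || p >= len) continue;
          acc += kern[q + r] * line[p];
          wsum += kern[q + r];
        }
        v[base + (size_t)i * st] = acc / wsum;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  std::vector<double> v(vol.begin(), vol.end());
  for (int ax = 0; ax < 3; ax++)
    smooth_axis(v, dim[0], dim[1], dim[2], ax, sigma_vox[ax]);
  return NumericVector(v.begin(), v.end());
}

// Central-difference spatial gradient, mm^-1 scale; returns n x 3.
// [[Rcpp::export]]
NumericVector gradient_cpp(NumericVector vol, IntegerVector dim,
                           NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  NumericVector out(n * 3);
  double *gx = out.begin(), *gy = gx + n, *gz = gy + n;
  const double *v = vol.begin();
  size_t s2 = (size_t)n1, s3 = (size_t)n1 * n2;
  size_t idx = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++, idx++) {
        int ip = i < n1 - 1 ? 1 : 0, im = i > 0 ? 1 : 0;
        int jp = j < n2 - 1 ? 1 : 0, jm = j > 0 ? 1 : 0;
        int kp = k < n3 - 1 ? 1 : 0, km = k > 0 ? 1 : 0;
        gx[idx] = (v[idx + ip] - v[idx - im]) / ((ip + im) * spacing[0]);
        gy[idx] = (v[idx + jp * s2] - v[idx - jm * s2]) / ((jp + jm) * spacing[1]);
        gz[idx] = (v[idx + kp * s3] - v[idx - km * s3]) / ((kp + km) * spacing[2]);
      }
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform with spacing h.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double qq = (double)q * h;
    double s;
    while (true) {
      double vq = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vq * vq)) / (2 * qq - 2 * vq);
      if (s <= z[k]) {
        k--;
      } else
        break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) k++;
    double vq = (double)v[k] * h;
    d[q] = (qq - vq) * (qq - vq) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : INF;
  size_t strides[3] = {1, (size_t)n1, (size_t)n1 * n2};
  int dims[3] = {n1, n2, n3};
  for (int axis = 0; axis < 3; axis++) {
    int len = dims[axis];
    size_t st = strides[axis];
    int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
    std::vector<double> f(len), d(len);
    for (int b = 0; b < dims[o2]; b++)
      for (int a = 0; a < dims[o1]; a++) {
        size_t base = (size_t)a * strides[o1] + (size_t)b * strides[o2];
        for (int i = 0; i < len; i++) f[i] = g[base + (size_t)i * st];
        dt1d(f, d, len, spacing[axis]);
        for (int i = 0; i < len; i++) g[base + (size_t)i * st] = d[i];
      }
  }
  return NumericVector(g.begin(), g.end());
}

// Joint histogram with linear (triangular) kernel in bin space; rows = a.
// [[Rcpp::export]]
NumericMatrix hist2d_parzen_cpp(NumericVector a, NumericVector b, int nbins,
                                double amin, double amax, double bmin,
                                double bmax) {
  NumericMatrix H(nbins, nbins);
  double ascale = (nbins - 1) / std::max(amax - amin, 1e-12);
  double bscale = (nbins - 1) / std::max(bmax - bmin, 1e-12);
  size_t n = a.size();
  for (size_t i = 0; i < n; i++) {
    double ca = (a[i] - amin) * ascale, cb = (b[i] - bmin) * bscale;
    if (ca < 0) ca = 0;
    if (cb < 0) cb = 0;
    if (ca > nbins - 1) ca = nbins - 1;
    if (cb > nbins - 1) cb = nbins - 1;
    int ia = (int)std::floor(ca), ib = (int)std::floor(cb);
    if (ia == nbins - 1) ia--;
    if (ib == nbins - 1) ib--;
    if (ia < 0) ia = 0;
    if (ib < 0) ib = 0;
    double fa = ca - ia, fb = cb - ib;
    H(ia, ib) += (1 - fa) * (1 - fb);
    H(ia + 1, ib) += fa * (1 - fb);
    H(ia, ib + 1) += (1 - fa) * fb;
    H(ia + 1, ib + 1) += fa * fb;
  }
  return H;
}

// Brute-force nearest neighbour: index (1-based) into ref for each query row.
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  IntegerVector out(nq);
  for (int i = 0; i < nq; i++) {
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int j = 0; j < nr; j++) {
      double acc = 0;
      for (int c = 0; c < d; c++) {
        double t = query(i, c) - ref(j, c);
        acc += t * t;
        if (acc >= best) break;
      }
      if (acc < best) {
        best = acc;
        bi = j;
      }
    }
    out[i] = bi + 1;
  }
  return out;
}
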