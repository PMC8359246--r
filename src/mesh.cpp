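#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra: each grid cell is split into
// six tetrahedra around the main diagonal (a decomposition that is consistent
// across neighbouring cells, so the surface is watertight). Vertices lie on
// cell edges at linear interpolation of the iso level and are de-duplicated by
// edge key, in physical mm coordinates. Triangles are oriented with outward
// normals (away from the super-level set).

struct MeshAcc {
  std::map<std::pair<size_t, size_t>, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static int edge_vertex(MeshAcc &m, size_t ia, size_t ib, const double *pa,
                       const double *pb, double fa, double fb, double iso) {
  std::pair<size_t, size_t> key = ia < ib ? std::make_pair(ia, ib)
                                          : std::make_pair(ib, ia);
  auto it = m.edge_vert.find(key);
  if (it != m.edge_vert.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)m.vx.size();  // 1-based
  m.edge_vert[key] = id;
  return id;
}

static void add_tri(MeshAcc &m, int a, int b, int c, const double *inward) {
  // orient so the normal points away from the interior point `inward`
  double ax = m.vx[a - 1], ay = m.vy[a - 1], az = m.vz[a - 1];
  double ux = m.vx[b - 1] - ax, uy = m.vy[b - 1] - ay, uz = m.vz[b - 1] - az;
  double wx = m.vx[c - 1] - ax, wy = m.vy[c - 1] - ay, wz = m.vz[c - 1] - az;
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double dx = ax - inward[0], dy = ay - inward[1], dz = az - inward[2];
  if (nx * dx + ny * dy + nz * dz < 0) std::swap(b, c);
  m.tri.push_back(a);
  m.tri.push_back(b);
  m.tri.push_back(c);
}

static void do_tet(MeshAcc &m, const size_t id[4], const double p[4][3],
                   const double f[4], double iso) {
  int inside[4], ni = 0, no = 0, in_idx[4], out_idx[4];
  for (int i = 0; i < 4; i++) {
    inside[i] = f[i] > iso;
    if (inside[i]) in_idx[ni++] = i; else out_idx[no++] = i;
  }
  if (ni == 0 || ni == 4) return;
  // interior reference point = mean of inside corners
  double cin[3] = {0, 0, 0};
  for (int q = 0; q < ni; q++)
    for (int c = 0; c < 3; c++) cin[c] += p[in_idx[q]][c] / ni;
  if (ni == 1 || ni == 3) {
    int apex = ni == 1 ? in_idx[0] : out_idx[0];
    int others[3], t = 0;
    for (int i = 0; i < 4; i++)
      if (i != apex) others[t++] = i;
    int v[3];
    for (int q = 0; q < 3; q++)
      v[q] = edge_vertex(m, id[apex], id[others[q]], p[apex], p[others[q]],
                         f[apex], f[others[q]], iso);
    add_tri(m, v[0], v[1], v[2], cin);
  } else {
    // two inside, two outside: quad split into two triangles
    int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
    int vac = edge_vertex(m, id[a], id[c], p[a], p[c], f[a], f[c], iso);
    int vad = edge_vertex(m, id[a], id[d], p[a], p[d], f[a], f[d], iso);
    int vbc = edge_vertex(m, id[b], id[c], p[b], p[c], f[b], f[c], iso);
    int vbd = edge_vertex(m, id[b], id[d], p[b], p[d], f[b], f[d], iso);
    add_tri(m, vac, vad, vbd, cin);
    add_tri(m, vac, vbd, vbc, cin);
  }
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, double iso) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t s2 = (size_t)n1, s3 = (size_t)n1 * n2;
  // cube corner offsets (x, y, z)
  const int co[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                        {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  MeshAcc m;
  const double *v = vol.begin();
  for (int k = 0; k < n3 - 1; k++)
    for (int j = 0; j < n2 - 1; j++)
      for (int i = 0; i < n1 - 1; i++) {
        size_t cid[8];
        double cp[8][3], cf[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int x = i + co[c][0], y = j + co[c][1], z = k + co[c][2];
          cid[c] = (size_t)x + (size_t)y * s2 + (size_t)z * s3;
          cp[c][0] = x * spacing[0];
          cp[c][1] = y * spacing[1];
          cp[c][2] = z * spacing[2];
          cf[c] = v[cid[c]];
          if (cf[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          size_t tid[4];
          double tp[4][3], tf[4];
          for (int q = 0; q < 4; q++) {
            tid[q] = cid[tets[t][q]];
            for (int c = 0; c < 3; c++) tp[q][c] = cp[tets[t][q]][c];
            tf[q] = cf[tets[t][q]];
          }
          do_tet(m, tid, tp, tf, iso);
        }
      }
  int nv = (int)m.vx.size(), nf = (int)(m.tri.size() / 3);
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nv; i++) {
    verts(i, 0) = m.vx[i];
    verts(i, 1) = m.vy[i];
    verts(i, 2) = m.vz[i];
  }
  for (int i = 0; i < nf; i++)
    for (int c = 0; c < 3; c++) faces(i, c) = m.tri[3 * i + c];
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
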