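#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a Kuhn 6-tet cube split.
// The split shares its face diagonals between neighbouring cubes (all tets
// contain the main diagonal c0-c7 of their cube), so the emitted surface is
// combinatorially watertight as long as the level set does not touch the
// grid boundary -- callers pad the field with a negative layer.
//
// Solid convention: s >= 0 is inside.  Triangles are oriented with outward
// normals (solid -> void).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static inline int interp_vertex(MTState &st, uint64_t ga, uint64_t gb,
                                double va, double vb,
                                const double *pa, const double *pb) {
  uint64_t key = ga < gb ? ga * 0x100000000ULL + gb : gb * 0x100000000ULL + ga;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = va / (va - vb);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static inline void push_tri(MTState &st, int a, int b, int c,
                            const double *dir) {
  // orient so the normal has positive component along dir (inside->outside)
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * dir[0] + ny * dir[1] + nz * dir[2] < 0.0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector s, IntegerVector dims,
                             double h, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *sv = REAL(s);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // the 6 tetrahedra of the Kuhn split, as cube-corner indices (x + 2y + 4z)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  MTState st;
  double P[8][3];
  double V[8];
  uint64_t G[8];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int npos = 0, nneg = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          uint64_t gid = (uint64_t)ci + (uint64_t)nx * ((uint64_t)cj + (uint64_t)ny * ck);
          G[c] = gid;
          V[c] = sv[gid];
          P[c][0] = ox + h * ci; P[c][1] = oy + h * cj; P[c][2] = oz + h * ck;
          if (V[c] >= 0.0) ++npos; else ++nneg;
        }
        if (npos == 8 || nneg == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0;
          for (int m = 0; m < 4; ++m) if (V[T[m]] >= 0.0) in[nin++] = m;
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // apex corner: the lone inside (nin==1) or lone outside (nin==3)
            int apex = -1;
            if (nin == 1) apex = in[0];
            else for (int m = 0; m < 4; ++m) if (V[T[m]] < 0.0) apex = m;
            int others[3], no = 0;
            for (int m = 0; m < 4; ++m) if (m != apex) others[no++] = m;
            int a = T[apex];
            int e[3];
            for (int m = 0; m < 3; ++m) {
              int b = T[others[m]];
              e[m] = interp_vertex(st, G[a], G[b], V[a], V[b], P[a], P[b]);
            }
            double cx = (st.vx[e[0]] + st.vx[e[1]] + st.vx[e[2]]) / 3.0;
            double cy = (st.vy[e[0]] + st.vy[e[1]] + st.vy[e[2]]) / 3.0;
            double cz = (st.vz[e[0]] + st.vz[e[1]] + st.vz[e[2]]) / 3.0;
            double dir[3];
            if (nin == 1) { // outward = away from the inside apex
              dir[0] = cx - P[a][0]; dir[1] = cy - P[a][1]; dir[2] = cz - P[a][2];
            } else {        // outward = toward the outside apex
              dir[0] = P[a][0] - cx; dir[1] = P[a][1] - cy; dir[2] = P[a][2] - cz;
            }
            push_tri(st, e[0], e[1], e[2], dir);
          } else { // nin == 2: quad split into two triangles
            int A = T[in[0]], B = T[in[1]];
            int out[2], no = 0;
            for (int m = 0; m < 4; ++m) if (V[T[m]] < 0.0) out[no++] = m;
            int C = T[out[0]], D = T[out[1]];
            int vAC = interp_vertex(st, G[A], G[C], V[A], V[C], P[A], P[C]);
            int vAD = interp_vertex(st, G[A], G[D], V[A], V[D], P[A], P[D]);
            int vBD = interp_vertex(st, G[B], G[D], V[B], V[D], P[B], P[D]);
            int vBC = interp_vertex(st, G[B], G[C], V[B], V[C], P[B], P[C]);
            double dir[3] = {
              (P[C][0] + P[D][0] - P[A][0] - P[B][0]) * 0.5,
              (P[C][1] + P[D][1] - P[A][1] - P[B][1]) * 0.5,
              (P[C][2] + P[D][2] - P[A][2] - P[B][2]) * 0.5
            };
            push_tri(st, vAC, vAD, vBD, dir);
            push_tri(st, vAC, vBD, vBC, dir);
          }
        }
      }

  int nV = (int)st.vx.size(), nF = (int)st.f0.size();
  NumericMatrix verts(nV, 3);
  for (int v = 0; v < nV; ++v) {
    verts(v, 0) = st.vx[v]; verts(v, 1) = st.vy[v]; verts(v, 2) = st.vz[v];
  }
  IntegerMatrix faces(nF, 3);
  for (int f = 0; f < nF; ++f) {
    faces(f, 0) = st.f0[f] + 1; faces(f, 1) = st.f1[f] + 1; faces(f, 2) = st.f2[f] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Number of mesh edges not shared by exactly two faces (0 for watertight).
// [[Rcpp::export]]
int cpp_open_edge_count(IntegerMatrix faces) {
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve(faces.nrow() * 2);
  for (int f = 0; f < faces.nrow(); ++f) {
    for (int e = 0; e < 3; ++e) {
      uint64_t a = faces(f, e), b = faces(f, (e + 1) % 3);
      uint64_t key = a < b ? a * 0x100000000ULL + b : b * 0x100000000ULL + a;
      ++cnt[key];
    }
  }
  int open = 0;
  for (auto &kv : cnt) if (kv.second != 2) ++open;
  return open;
}

// Signed mesh volume by the divergence theorem (sum of origin-tetrahedra).
// [[Rcpp::export]]
double cpp_mesh_volume(NumericMatrix verts, IntegerMatrix faces) {
  double vol = 0.0;
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    vol += ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx);
  }
  return vol / 6.0;
}

// Connected-component labeling of the foreground (pixels == 1) of a binary
// image, 4- or 8-connectivity, stack-based fill.  Background and NA -> 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix img, int connectivity) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  static const int d4r[] = {-1, 1, 0, 0},          d4c[] = {0, 0, -1, 1};
  static const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1},
                   d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? d8r : d4r;
  const int *dc = connectivity == 8 ? d8c : d4c;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (img(r0, c0) != 1 || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + nr * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int d = 0; d < nd; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (img(rr, cc) == 1 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + nr * cc);
          }
        }
      }
    }
  return lab;
}
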