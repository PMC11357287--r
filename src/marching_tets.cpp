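#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// Extract the zero level set of a scalar field sampled on a regular grid.
// Each grid cell is split into six tetrahedra sharing the cube's main
// diagonal; the split is translation-invariant, so the face diagonals of
// adjacent cells coincide and the extracted surface is watertight wherever
// the level set stays inside the grid. Within a tetrahedron the field is
// linear, so intersection points sit on tet edges and triangle orientation
// can be fixed exactly against the (constant) per-tet field gradient.
//
// Surface vertices are welded by the pair of grid-node ids spanning the
// edge they lie on: no epsilon merging is needed.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}

inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}

inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

}  // namespace

// [[Rcpp::export(name = ".marching_tets_cpp")]]
Rcpp::List marching_tets_cpp(Rcpp::NumericVector field, int nx, int ny, int nz,
                             Rcpp::NumericVector origin, double h) {
  if (nx < 2 || ny < 2 || nz < 2)
    Rcpp::stop("grid must have at least 2 nodes per axis");
  const double* f = field.begin();
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // cube corner offsets (i, j, k)
  static const int coff[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // six tets around the 0-6 diagonal
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based vertex indices, 3 per face

  auto node_id = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  // vertex on the edge between grid nodes a and b (field values fa, fb)
  auto edge_point = [&](int64_t a, int64_t b, double fa, double fb,
                        const Vec3& pa, const Vec3& pb) -> int {
    uint64_t key;
    if (a < b)
      key = ((uint64_t)a << 32) | (uint64_t)b;
    else
      key = ((uint64_t)b << 32) | (uint64_t)a;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = fa / (fa - fb);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int idx = (int)vx.size();
    vx.push_back(pa.x + t * (pb.x - pa.x));
    vy.push_back(pa.y + t * (pb.y - pa.y));
    vz.push_back(pa.z + t * (pb.z - pa.z));
    edge_vertex.emplace(key, idx);
    return idx;
  };

  int64_t cid[8];
  double cf[8];
  Vec3 cp[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + coff[c][0], jj = j + coff[c][1], kk = k + coff[c][2];
          cid[c] = node_id(ii, jj, kk);
          cf[c] = f[cid[c]];
          cp[c] = Vec3{ox + h * ii, oy + h * jj, oz + h * kk};
          if (cf[c] < 0)
            any_neg = true;
          else
            any_pos = true;
        }
        if (!any_neg || !any_pos) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (cf[T[c]] < 0) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;

          // exact gradient of the linear field on this tet
          Vec3 e1 = cp[T[1]] - cp[T[0]];
          Vec3 e2 = cp[T[2]] - cp[T[0]];
          Vec3 e3 = cp[T[3]] - cp[T[0]];
          double d1 = cf[T[1]] - cf[T[0]];
          double d2 = cf[T[2]] - cf[T[0]];
          double d3 = cf[T[3]] - cf[T[0]];
          Vec3 c23 = cross(e2, e3), c31 = cross(e3, e1), c12 = cross(e1, e2);
          double vol6 = dot(e1, c23);
          Vec3 grad{(d1 * c23.x + d2 * c31.x + d3 * c12.x) / vol6,
                    (d1 * c23.y + d2 * c31.y + d3 * c12.y) / vol6,
                    (d1 * c23.z + d2 * c31.z + d3 * c12.z) / vol6};

          auto ep = [&](int a, int b) -> int {
            return edge_point(cid[T[a]], cid[T[b]], cf[T[a]], cf[T[b]],
                              cp[T[a]], cp[T[b]]);
          };
          auto emit = [&](int a, int b, int c) {
            Vec3 pa{vx[a], vy[a], vz[a]};
            Vec3 pb{vx[b], vy[b], vz[b]};
            Vec3 pc{vx[c], vy[c], vz[c]};
            Vec3 nrm = cross(pb - pa, pc - pa);
            // outward normal points toward increasing field
            if (dot(nrm, grad) >= 0) {
              tri.push_back(a); tri.push_back(b); tri.push_back(c);
            } else {
              tri.push_back(a); tri.push_back(c); tri.push_back(b);
            }
          };

          if (nin == 1) {
            int v0 = inside[0];
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != v0) o[m++] = c;
            emit(ep(v0, o[0]), ep(v0, o[1]), ep(v0, o[2]));
          } else if (nin == 3) {
            int v0 = -1;
            for (int c = 0; c < 4; ++c) {
              bool is_in = false;
              for (int q = 0; q < 3; ++q)
                if (inside[q] == c) is_in = true;
              if (!is_in) v0 = c;
            }
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != v0) o[m++] = c;
            emit(ep(v0, o[0]), ep(v0, o[1]), ep(v0, o[2]));
          } else {  // nin == 2: quad split into two triangles
            int a = inside[0], b = inside[1];
            int o[2], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a && c != b) o[m++] = c;
            int p00 = ep(a, o[0]), p01 = ep(a, o[1]);
            int p10 = ep(b, o[0]), p11 = ep(b, o[1]);
            emit(p00, p01, p11);
            emit(p00, p11, p10);
          }
        }
      }
    }
  }

  int nv = (int)vx.size();
  int nf = (int)tri.size() / 3;
  Rcpp::NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v];
    V(v, 1) = vy[v];
    V(v, 2) = vz[v];
  }
  Rcpp::IntegerMatrix Fm(nf, 3);
  for (int q = 0; q < nf; ++q) {
    Fm(q, 0) = tri[3 * q] + 1;
    Fm(q, 1) = tri[3 * q + 1] + 1;
    Fm(q, 2) = tri[3 * q + 2] + 1;
  }
  return Rcpp::List::create(Rcpp::Named("vertices") = V,
                            Rcpp::Named("faces") = Fm);
}
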