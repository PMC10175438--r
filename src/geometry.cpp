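#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labelling of a 3D binary mask (6/18/26 connectivity).
// Components are relabelled 1..K by decreasing voxel count (ties: discovery
// order), matching the convention that fragment 1 is the largest fragment.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> comp_size;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(start);
    labels[start] = next_label;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++size;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < odx.size(); ++o) {
        int xx = x + odx[o], yy = y + ody[o], zz = z + odz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
    comp_size.push_back(size);
  }

  // rank labels by decreasing size, stable in discovery order
  std::vector<int> order(next_label);
  for (int i = 0; i < next_label; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return comp_size[a] > comp_size[b]; });
  std::vector<int> remap(next_label + 1, 0);
  for (int r = 0; r < next_label; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] != 0) labels[i] = remap[labels[i]];

  labels.attr("n_components") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching tetrahedra.
//
// Each grid cell (between 8 neighbouring voxel centres) is decomposed into
// six tetrahedra sharing the c0-c6 body diagonal; this decomposition places
// matching diagonals on the shared faces of neighbouring cells, so the
// resulting mesh is watertight. The field is implicitly padded with zeros so
// that regions touching the array border are closed. Vertices are merged via
// the lattice edge they lie on; triangles are oriented with outward normals
// (pointing from values above the iso level towards values below).
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> t1, t2, t3;
};

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    double iso = 0.5) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int Px = nx + 2, Py = ny + 2, Pz = nz + 2;

  auto value = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0.0;
    return field[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  auto node_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)(i + 1) +
           (uint64_t)Px * ((uint64_t)(j + 1) + (uint64_t)Py * (uint64_t)(k + 1));
  };

  // cube corner offsets, c0..c7
  static const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra around the c0-c6 diagonal
  static const int TET[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  MTState st;

  double cpx[8], cpy[8], cpz[8], cv[8];
  uint64_t cid[8];

  auto edge_vert = [&](int a, int b) -> int {
    uint64_t ia = cid[a], ib = cid[b];
    uint64_t lo = ia < ib ? ia : ib, hi = ia < ib ? ib : ia;
    uint64_t key = lo * (uint64_t)(Px) * Py * Pz + hi;
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double va = cv[a], vb = cv[b];
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    int idx = (int)st.vx.size();
    st.vx.push_back(cpx[a] + t * (cpx[b] - cpx[a]));
    st.vy.push_back(cpy[a] + t * (cpy[b] - cpy[a]));
    st.vz.push_back(cpz[a] + t * (cpz[b] - cpz[a]));
    st.edge_vertex.emplace(key, idx);
    return idx;
  };

  auto emit = [&](int e1, int e2, int e3, int inside_corner) {
    double ax = st.vx[e1], ay = st.vy[e1], az = st.vz[e1];
    double ux = st.vx[e2] - ax, uy = st.vy[e2] - ay, uz = st.vz[e2] - az;
    double wx = st.vx[e3] - ax, wy = st.vy[e3] - ay, wz = st.vz[e3] - az;
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double cx0 = (ax + st.vx[e2] + st.vx[e3]) / 3.0 - cpx[inside_corner];
    double cy0 = (ay + st.vy[e2] + st.vy[e3]) / 3.0 - cpy[inside_corner];
    double cz0 = (az + st.vz[e2] + st.vz[e3]) / 3.0 - cpz[inside_corner];
    double d = nxv * cx0 + nyv * cy0 + nzv * cz0;
    if (d < 0) std::swap(e2, e3);
    st.t1.push_back(e1 + 1);
    st.t2.push_back(e2 + 1);
    st.t3.push_back(e3 + 1);
  };

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CX[c], cj = j + CY[c], ck = k + CZ[c];
          cv[c] = value(ci, cj, ck);
          if (cv[c] > iso) ++n_in;
          cpx[c] = ox + ci * sx;
          cpy[c] = oy + cj * sy;
          cpz[c] = oz + ck * sz;
          cid[c] = node_id(ci, cj, ck);
        }
        if (n_in == 0 || n_in == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int a = TET[t][0], b = TET[t][1], c = TET[t][2], d = TET[t][3];
          int corners[4] = {a, b, c, d};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int m = 0; m < 4; ++m) {
            if (cv[corners[m]] > iso) ins[ni++] = corners[m];
            else outs[no++] = corners[m];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            int e1 = edge_vert(ins[0], outs[0]);
            int e2 = edge_vert(ins[0], outs[1]);
            int e3 = edge_vert(ins[0], outs[2]);
            emit(e1, e2, e3, ins[0]);
          } else if (ni == 3) {
            int e1 = edge_vert(ins[0], outs[0]);
            int e2 = edge_vert(ins[1], outs[0]);
            int e3 = edge_vert(ins[2], outs[0]);
            emit(e1, e2, e3, ins[0]);
          } else { // ni == 2
            int eac = edge_vert(ins[0], outs[0]);
            int ead = edge_vert(ins[0], outs[1]);
            int ebd = edge_vert(ins[1], outs[1]);
            int ebc = edge_vert(ins[1], outs[0]);
            emit(eac, ead, ebd, ins[0]);
            emit(eac, ebd, ebc, ins[0]);
          }
        }
      }

  int nv = (int)st.vx.size(), nt = (int)st.t1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix Tm(nt, 3);
  for (int i = 0; i < nt; ++i) {
    Tm(i, 0) = st.t1[i]; Tm(i, 1) = st.t2[i]; Tm(i, 2) = st.t3[i];
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// ---------------------------------------------------------------------------
// 2D polygon utilities: simplicity test and ear-clipping triangulation.
// ---------------------------------------------------------------------------

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy,
                          double eps) {
  double d1 = cross2(cx, cy, dx, dy, ax, ay);
  double d2 = cross2(cx, cy, dx, dy, bx, by);
  double d3 = cross2(ax, ay, bx, by, cx, cy);
  double d4 = cross2(ax, ay, bx, by, dx, dy);
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps)))
    return true;
  return false;
}

// [[Rcpp::export(name = ".polygon_simple_cpp")]]
bool polygon_simple_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) return false;
  double span = 0.0;
  for (int i = 0; i < n; ++i) {
    span = std::max(span, std::abs(pts(i, 0)));
    span = std::max(span, std::abs(pts(i, 1)));
  }
  double eps = 1e-12 * std::max(1.0, span * span);
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue; // adjacent share a vertex
      if (seg_intersect(pts(i, 0), pts(i, 1), pts(i2, 0), pts(i2, 1),
                        pts(j, 0), pts(j, 1), pts(j2, 0), pts(j2, 1), eps))
        return false;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".earclip_cpp")]]
IntegerMatrix earclip_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) return IntegerMatrix(0, 3);

  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); }

  // ensure counter-clockwise orientation
  double area2 = 0.0, span = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    area2 += x[i] * y[j] - x[j] * y[i];
    span = std::max(span, std::max(std::abs(x[i]), std::abs(y[i])));
  }
  const double eps = 1e-12 * std::max(1.0, span * span);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  if (area2 < 0) std::reverse(idx.begin(), idx.end());

  std::vector<int> tri_out1, tri_out2, tri_out3;
  std::vector<int> active = idx;
  auto is_ear = [&](int pi, int ci, int ni) -> int {
    double cr = cross2(x[pi], y[pi], x[ci], y[ci], x[ni], y[ni]);
    if (cr < -eps) return -1; // reflex
    // any other active vertex strictly inside?
    for (size_t m = 0; m < active.size(); ++m) {
      int v = active[m];
      if (v == pi || v == ci || v == ni) continue;
      double c1 = cross2(x[pi], y[pi], x[ci], y[ci], x[v], y[v]);
      double c2 = cross2(x[ci], y[ci], x[ni], y[ni], x[v], y[v]);
      double c3 = cross2(x[ni], y[ni], x[pi], y[pi], x[v], y[v]);
      if (c1 > eps && c2 > eps && c3 > eps) return -2;
    }
    return 1;
  };

  // triangle quality: normalized area (4*sqrt(3)*A / sum of squared edges),
  // 1 for equilateral, 0 for degenerate; picking the best ear avoids
  // sliver triangles along nearly collinear stretches
  auto quality = [&](int a, int b, int c) -> double {
    double area2 = std::abs(cross2(x[a], y[a], x[b], y[b], x[c], y[c]));
    double l1 = (x[b]-x[a])*(x[b]-x[a]) + (y[b]-y[a])*(y[b]-y[a]);
    double l2 = (x[c]-x[b])*(x[c]-x[b]) + (y[c]-y[b])*(y[c]-y[b]);
    double l3 = (x[a]-x[c])*(x[a]-x[c]) + (y[a]-y[c])*(y[a]-y[c]);
    double s = l1 + l2 + l3;
    return s > 0 ? 1.1547 * area2 / s : 0.0;
  };

  int guard = 0, guard_max = n * n + 1000;
  while (active.size() > 3 && guard++ < guard_max) {
    bool clipped = false;
    int m = (int)active.size();
    int best_i = -1;
    double best_q = -1.0;
    for (int i = 0; i < m; ++i) {
      int pi = active[(i + m - 1) % m], ci = active[i], ni = active[(i + 1) % m];
      if (is_ear(pi, ci, ni) == 1) {
        double q = quality(pi, ci, ni);
        if (q > best_q) { best_q = q; best_i = i; }
      }
    }
    if (best_i >= 0) {
      int pi = active[(best_i + m - 1) % m], ci = active[best_i],
          ni = active[(best_i + 1) % m];
      tri_out1.push_back(pi); tri_out2.push_back(ci); tri_out3.push_back(ni);
      active.erase(active.begin() + best_i);
      clipped = true;
    }
    if (!clipped) {
      // numerical fallback: clip the first strictly convex vertex, else fan
      int m2 = (int)active.size();
      int pick = -1;
      for (int i = 0; i < m2; ++i) {
        int pi = active[(i + m2 - 1) % m2], ci = active[i],
            ni = active[(i + 1) % m2];
        if (cross2(x[pi], y[pi], x[ci], y[ci], x[ni], y[ni]) > eps) {
          pick = i; break;
        }
      }
      if (pick < 0) break;
      int pi = active[(pick + m2 - 1) % m2], ci = active[pick],
          ni = active[(pick + 1) % m2];
      tri_out1.push_back(pi); tri_out2.push_back(ci); tri_out3.push_back(ni);
      active.erase(active.begin() + pick);
    }
  }
  if (active.size() == 3) {
    tri_out1.push_back(active[0]);
    tri_out2.push_back(active[1]);
    tri_out3.push_back(active[2]);
  }

  int nt = (int)tri_out1.size();
  IntegerMatrix Tm(nt, 3);
  for (int i = 0; i < nt; ++i) {
    Tm(i, 0) = tri_out1[i] + 1;
    Tm(i, 1) = tri_out2[i] + 1;
    Tm(i, 2) = tri_out3[i] + 1;
  }
  return Tm;
}

// ---------------------------------------------------------------------------
// Minimum distance from each query point to a set of 3D segments, with the
// nearest point returned. Segments given as matched rows of A (start) and B
// (end).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".point_segments_dist_cpp")]]
List point_segments_dist_cpp(NumericMatrix pts, NumericMatrix segA,
                             NumericMatrix segB) {
  int np = pts.nrow(), ns = segA.nrow();
  NumericVector dist(np);
  NumericMatrix nearest(np, 3);
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf, bx = NA_REAL, by = NA_REAL, bz = NA_REAL;
    for (int s = 0; s < ns; ++s) {
      double ax = segA(s, 0), ay = segA(s, 1), az = segA(s, 2);
      double ux = segB(s, 0) - ax, uy = segB(s, 1) - ay, uz = segB(s, 2) - az;
      double L2 = ux * ux + uy * uy + uz * uz;
      double t = 0.0;
      if (L2 > 0) {
        t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double qx = ax + t * ux, qy = ay + t * uy, qz = az + t * uz;
      double dx = px - qx, dy = py - qy, dz = pz - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bx = qx; by = qy; bz = qz; }
    }
    dist[i] = std::sqrt(best);
    nearest(i, 0) = bx; nearest(i, 1) = by; nearest(i, 2) = bz;
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}
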