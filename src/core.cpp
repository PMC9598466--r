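// Geometric and image-sampling primitives used across the package.
// All mesh/face indices crossing the R boundary are 1-based; voxel
// coordinates passed to the samplers are 0-based (R side converts).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double sqr(double x) { return x * x; }

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour sampling of a 3-D array at fractional
// 0-based voxel coordinates. Points outside the grid return `outside`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix pts,
                                   double outside) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 &&
          z <= nz - 1)) {
      out[i] = outside;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const int sx = 1, sy = nx, sz = nx * ny;
    const double *p = v + x0 * sx + y0 * sy + (size_t)z0 * sz;
    double c00 = p[0] * (1 - fx) + p[sx] * fx;
    double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
    double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
    double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, NumericMatrix pts,
                                 double outside) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int i = 0; i < n; ++i) {
    int x = (int)std::lround(pts(i, 0));
    int y = (int)std::lround(pts(i, 1));
    int z = (int)std::lround(pts(i, 2));
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
      out[i] = outside;
    else
      out[i] = v[x + (size_t)nx * (y + (size_t)ny * z)];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact closest point on a triangle (Ericson, Real-Time Collision Detection).
// ---------------------------------------------------------------------------
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + t * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + t * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + t * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// ---------------------------------------------------------------------------
// Closest point on a triangle mesh for a set of query points, accelerated by
// a uniform-grid triangle bin (triangles inserted into every cell their AABB
// overlaps; expanding-shell search with a conservative termination bound).
// ---------------------------------------------------------------------------

struct MeshIndex {
  std::vector<double> vx;
  std::vector<int> fa;
  int nf;
  double lo[3], hi[3], h;
  int gd[3];
  std::vector<std::vector<int> > bins;

  int cell_of(double x, int j) const {
    int c = (int)std::floor((x - lo[j]) / h);
    if (c < 0) c = 0;
    if (c >= gd[j]) c = gd[j] - 1;
    return c;
  }
  size_t bin_idx(int i, int j, int k) const {
    return (size_t)i + (size_t)gd[0] * (j + (size_t)gd[1] * k);
  }
};

static MeshIndex *build_index(NumericMatrix V, IntegerMatrix Fc) {
  const int nf = Fc.nrow(), nv = V.nrow();
  if (nf == 0 || nv == 0) stop("empty mesh");
  MeshIndex *mi = new MeshIndex();
  mi->nf = nf;
  mi->vx.resize(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) mi->vx[3 * i + j] = V(i, j);
  mi->fa.resize(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) {
      int idx = Fc(i, j) - 1;
      if (idx < 0 || idx >= nv) {
        delete mi;
        stop("face index out of range");
      }
      mi->fa[3 * i + j] = idx;
    }
  for (int j = 0; j < 3; ++j) {
    mi->lo[j] = R_PosInf;
    mi->hi[j] = R_NegInf;
  }
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) {
      if (mi->vx[3 * i + j] < mi->lo[j]) mi->lo[j] = mi->vx[3 * i + j];
      if (mi->vx[3 * i + j] > mi->hi[j]) mi->hi[j] = mi->vx[3 * i + j];
    }
  double ext = std::max(mi->hi[0] - mi->lo[0],
                        std::max(mi->hi[1] - mi->lo[1],
                                 mi->hi[2] - mi->lo[2]));
  if (ext <= 0) ext = 1.0;
  int G = (int)std::ceil(std::cbrt((double)nf / 4.0));
  if (G < 1) G = 1;
  if (G > 64) G = 64;
  mi->h = ext / G + 1e-12;
  for (int j = 0; j < 3; ++j)
    mi->gd[j] = std::max(1, (int)std::ceil((mi->hi[j] - mi->lo[j]) / mi->h));
  mi->bins.resize((size_t)mi->gd[0] * mi->gd[1] * mi->gd[2]);
  for (int f = 0; f < nf; ++f) {
    int cmin[3], cmax[3];
    for (int j = 0; j < 3; ++j) {
      double tlo = R_PosInf, thi = R_NegInf;
      for (int v = 0; v < 3; ++v) {
        double c = mi->vx[3 * mi->fa[3 * f + v] + j];
        if (c < tlo) tlo = c;
        if (c > thi) thi = c;
      }
      cmin[j] = mi->cell_of(tlo, j);
      cmax[j] = mi->cell_of(thi, j);
    }
    for (int k = cmin[2]; k <= cmax[2]; ++k)
      for (int jy = cmin[1]; jy <= cmax[1]; ++jy)
        for (int ix = cmin[0]; ix <= cmax[0]; ++ix)
          mi->bins[mi->bin_idx(ix, jy, k)].push_back(f);
  }
  return mi;
}

static List query_index(const MeshIndex *mi, NumericMatrix Q) {
  const int nq = Q.nrow();
  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector face(nq);
  const double h = mi->h;
  int maxshell = mi->gd[0] + mi->gd[1] + mi->gd[2] + 2;

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    int cq[3] = {mi->cell_of(p[0], 0), mi->cell_of(p[1], 1),
                 mi->cell_of(p[2], 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    for (int s = 0; s <= maxshell; ++s) {
      // cells at Chebyshev distance s from cq (clamped into the grid);
      // any cell at shell s is at least (s-1)*h away from p, so once
      // best <= (s-1)*h no further shell can improve it.
      if (bestf >= 0 && best <= (s - 1) * h) break;
      bool any = false;
      int i0 = std::max(0, cq[0] - s), i1 = std::min(mi->gd[0] - 1, cq[0] + s);
      int j0 = std::max(0, cq[1] - s), j1 = std::min(mi->gd[1] - 1, cq[1] + s);
      int k0 = std::max(0, cq[2] - s), k1 = std::min(mi->gd[2] - 1, cq[2] + s);
      for (int k = k0; k <= k1; ++k)
        for (int jy = j0; jy <= j1; ++jy)
          for (int ix = i0; ix <= i1; ++ix) {
            int cd = std::max(std::abs(ix - cq[0]),
                              std::max(std::abs(jy - cq[1]),
                                       std::abs(k - cq[2])));
            if (cd != s) continue;  // only the new shell
            any = true;
            const std::vector<int> &lst = mi->bins[mi->bin_idx(ix, jy, k)];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              double cp[3];
              closest_on_tri(p, &mi->vx[3 * mi->fa[3 * f]],
                             &mi->vx[3 * mi->fa[3 * f + 1]],
                             &mi->vx[3 * mi->fa[3 * f + 2]], cp);
              double d = std::sqrt(sqr(cp[0] - p[0]) + sqr(cp[1] - p[1]) +
                                   sqr(cp[2] - p[2]));
              if (d < best) {
                best = d;
                bestf = f;
                bestpt[0] = cp[0];
                bestpt[1] = cp[1];
                bestpt[2] = cp[2];
              }
            }
          }
      if (!any && s > 0 && bestf >= 0) break;  // grid exhausted
    }
    dist[q] = best;
    face[q] = bestf + 1;
    closest(q, 0) = bestpt[0];
    closest(q, 1) = bestpt[1];
    closest(q, 2) = bestpt[2];
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// [[Rcpp::export]]
SEXP cpp_mesh_index(NumericMatrix V, IntegerMatrix Fc) {
  XPtr<MeshIndex> ptr(build_index(V, Fc), true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_closest_point_query(SEXP index, NumericMatrix Q) {
  XPtr<MeshIndex> ptr(index);
  return query_index(ptr.get(), Q);
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix Fc,
                            NumericMatrix Q) {
  MeshIndex *mi = build_index(V, Fc);
  List out = query_index(mi, Q);
  delete mi;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: isosurface of a 3-D scalar field at level `iso`.
// Each grid cube is split into 6 tetrahedra sharing the main diagonal;
// surface vertices are created on lattice edges and welded via a hash map,
// so the output is a watertight shared-vertex mesh on closed level sets.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, double iso) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  auto gidx = [&](int x, int y, int z) {
    return (int64_t)x + (int64_t)nx * (y + (int64_t)ny * z);
  };

  // 6-tet decomposition of the cube, corners in local index 0..7
  static const int cube[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> verts;
  std::vector<int> faces;

  auto edge_point = [&](int64_t ga, int64_t gb, double fa_, double fb_,
                        int ax, int ay, int az, int bx, int by, int bz) {
    uint64_t key;
    if (ga < gb)
      key = ((uint64_t)ga << 32) | (uint64_t)gb;
    else
      key = ((uint64_t)gb << 32) | (uint64_t)ga;
    std::unordered_map<uint64_t, int>::iterator it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (iso - fa_) / (fb_ - fa_);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    verts.push_back(ax + t * (bx - ax));
    verts.push_back(ay + t * (by - ay));
    verts.push_back(az + t * (bz - az));
    int id = (int)(verts.size() / 3) - 1;
    edge_vert[key] = id;
    return id;
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double f[8];
        int64_t g[8];
        int cx[8], cy[8], cz[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          cx[c] = x + cube[c][0];
          cy[c] = y + cube[c][1];
          cz[c] = z + cube[c][2];
          g[c] = gidx(cx[c], cy[c], cz[c]);
          f[c] = v[g[c]];
          (f[c] >= iso) ? anyin = true : anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int in[4], ni = 0, outc[4], no = 0;
          int corner[4] = {a, b, c, d};
          for (int m = 0; m < 4; ++m) {
            if (f[corner[m]] >= iso)
              in[ni++] = corner[m];
            else
              outc[no++] = corner[m];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in[0] : outc[0];
            int others[3];
            int k = 0;
            for (int m = 0; m < 4; ++m)
              if (corner[m] != apex) others[k++] = corner[m];
            int e[3];
            for (int m = 0; m < 3; ++m)
              e[m] = edge_point(g[apex], g[others[m]], f[apex], f[others[m]],
                                cx[apex], cy[apex], cz[apex], cx[others[m]],
                                cy[others[m]], cz[others[m]]);
            if (e[0] != e[1] && e[1] != e[2] && e[0] != e[2]) {
              faces.push_back(e[0]);
              faces.push_back(e[1]);
              faces.push_back(e[2]);
            }
          } else {
            // two in (i0,i1), two out (o0,o1): quad (i0,o0)(i0,o1)(i1,o1)(i1,o0)
            int i0 = in[0], i1 = in[1], o0 = outc[0], o1 = outc[1];
            int e1 = edge_point(g[i0], g[o0], f[i0], f[o0], cx[i0], cy[i0],
                                cz[i0], cx[o0], cy[o0], cz[o0]);
            int e2 = edge_point(g[i0], g[o1], f[i0], f[o1], cx[i0], cy[i0],
                                cz[i0], cx[o1], cy[o1], cz[o1]);
            int e3 = edge_point(g[i1], g[o1], f[i1], f[o1], cx[i1], cy[i1],
                                cz[i1], cx[o1], cy[o1], cz[o1]);
            int e4 = edge_point(g[i1], g[o0], f[i1], f[o0], cx[i1], cy[i1],
                                cz[i1], cx[o0], cy[o0], cz[o0]);
            if (e1 != e2 && e2 != e3 && e1 != e3) {
              faces.push_back(e1);
              faces.push_back(e2);
              faces.push_back(e3);
            }
            if (e1 != e3 && e3 != e4 && e1 != e4) {
              faces.push_back(e1);
              faces.push_back(e3);
              faces.push_back(e4);
            }
          }
        }
      }

  int nvout = (int)(verts.size() / 3);
  int nfout = (int)(faces.size() / 3);
  NumericMatrix Vout(nvout, 3);
  for (int i = 0; i < nvout; ++i)
    for (int j = 0; j < 3; ++j) Vout(i, j) = verts[3 * i + j];
  IntegerMatrix Fout(nfout, 3);
  for (int i = 0; i < nfout; ++i)
    for (int j = 0; j < 3; ++j) Fout(i, j) = faces[3 * i + j] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Largest 6-connected component of a logical mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  const int *m = LOGICAL(mask);
  int nlab = 0;
  size_t best_size = 0;
  int best_lab = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++nlab;
    size_t sz = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = nlab;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      ++sz;
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny),
          z = (int)(cur / ((size_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t idx = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (m[idx] && !lab[idx]) {
          lab[idx] = nlab;
          stack.push_back(idx);
        }
      }
    }
    if (sz > best_size) {
      best_size = sz;
      best_lab = nlab;
    }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = dim;
  for (size_t s = 0; s < n; ++s) out[s] = (lab[s] == best_lab);
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation with a Euclidean ball of radius r voxels
// (erosion/closing are composed on the R side via complements).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, double r) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *m = LOGICAL(mask);
  LogicalVector out(mask.size());
  out.attr("dim") = dim;
  int ir = (int)std::floor(r);
  std::vector<int> off;
  for (int dz = -ir; dz <= ir; ++dz)
    for (int dy = -ir; dy <= ir; ++dy)
      for (int dx = -ir; dx <= ir; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r) {
          off.push_back(dx);
          off.push_back(dy);
          off.push_back(dz);
        }
  const int noff = (int)off.size() / 3;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
        if (!m[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          int xx = x + off[3 * o], yy = y + off[3 * o + 1],
              zz = z + off[3 * o + 2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          out[xx + (size_t)nx * (yy + (size_t)ny * zz)] = true;
        }
      }
  return out;
}
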