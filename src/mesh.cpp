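#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Closed surface mesh of a scalar field by marching tetrahedra.
//
// The field samples a function at voxel centres; the surface is the `level`
// isosurface of the piecewise-linear interpolant on the Kuhn
// (6-tetrahedra) decomposition of each cell between 8 neighbouring voxel
// centres. For a binary 0/1 field at level 0.5 every surface vertex lies at
// the midpoint of a cell edge. The field is conceptually padded with zeros
// so the mesh is closed; triangles are oriented outward, giving the
// enclosed volume by the divergence theorem.

namespace {

struct V3 {
  double x, y, z;
};

// linear interpolation of the level crossing on edge (a, b)
inline V3 crossing(const V3 &a, double va, const V3 &b, double vb,
                   double level) {
  double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return V3{a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
            a.z + t * (b.z - a.z)};
}

// Kuhn decomposition: 6 tetrahedra sharing the main diagonal c0-c7.
// Corner numbering: bit 0 -> +x, bit 1 -> +y, bit 2 -> +z.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshAcc {
  double area = 0.0, vol6 = 0.0;
  std::vector<double> verts; // x,y,z triples, per triangle corner

  void tri(const V3 &a, const V3 &b, const V3 &c, const V3 &in_pt) {
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
    double nx = uy * vz - uz * vy;
    double ny = uz * vx - ux * vz;
    double nz = ux * vy - uy * vx;
    // orient away from the inside point
    double cx = (a.x + b.x + c.x) / 3 - in_pt.x;
    double cy = (a.y + b.y + c.y) / 3 - in_pt.y;
    double cz = (a.z + b.z + c.z) / 3 - in_pt.z;
    V3 p1 = a, p2 = b, p3 = c;
    if (nx * cx + ny * cy + nz * cz < 0) {
      std::swap(p2, p3);
      nx = -nx; ny = -ny; nz = -nz;
    }
    area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
    // signed volume contribution of tetra (origin, p1, p2, p3)
    vol6 += p1.x * (p2.y * p3.z - p2.z * p3.y) -
            p1.y * (p2.x * p3.z - p2.z * p3.x) +
            p1.z * (p2.x * p3.y - p2.y * p3.x);
    verts.insert(verts.end(), {p1.x, p1.y, p1.z, p2.x, p2.y, p2.z,
                               p3.x, p3.y, p3.z});
  }

  void tet(const V3 p[4], const double v[4], double level) {
    bool in[4];
    int nin = 0;
    for (int q = 0; q < 4; ++q) {
      in[q] = v[q] > level;
      nin += in[q];
    }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4], ni = 0, no = 0;
    for (int q = 0; q < 4; ++q) {
      if (in[q]) ins[ni++] = q; else outs[no++] = q;
    }
    if (nin == 1 || nin == 3) {
      int apex = (nin == 1) ? ins[0] : outs[0];
      const int *oth = (nin == 1) ? outs : ins;
      V3 m0 = crossing(p[apex], v[apex], p[oth[0]], v[oth[0]], level);
      V3 m1 = crossing(p[apex], v[apex], p[oth[1]], v[oth[1]], level);
      V3 m2 = crossing(p[apex], v[apex], p[oth[2]], v[oth[2]], level);
      V3 in_pt = (nin == 1)
        ? p[ins[0]]
        : V3{(p[ins[0]].x + p[ins[1]].x + p[ins[2]].x) / 3,
             (p[ins[0]].y + p[ins[1]].y + p[ins[2]].y) / 3,
             (p[ins[0]].z + p[ins[1]].z + p[ins[2]].z) / 3};
      tri(m0, m1, m2, in_pt);
    } else { // 2 in, 2 out: quad split into two triangles
      V3 m00 = crossing(p[ins[0]], v[ins[0]], p[outs[0]], v[outs[0]], level);
      V3 m01 = crossing(p[ins[0]], v[ins[0]], p[outs[1]], v[outs[1]], level);
      V3 m11 = crossing(p[ins[1]], v[ins[1]], p[outs[1]], v[outs[1]], level);
      V3 m10 = crossing(p[ins[1]], v[ins[1]], p[outs[0]], v[outs[0]], level);
      V3 in_pt = V3{(p[ins[0]].x + p[ins[1]].x) / 2,
                    (p[ins[0]].y + p[ins[1]].y) / 2,
                    (p[ins[0]].z + p[ins[1]].z) / 2};
      tri(m00, m01, m11, in_pt);
      tri(m00, m11, m10, in_pt);
    }
  }
};

} // namespace

// field: 3D numeric array sampled at voxel centres; spacing: voxel size
// (mm). Voxel (i,j,k) (0-based) has centre ((i+0.5)*sx, ...). Returns
// surface area (mm^2), enclosed volume (mm^3) and the triangle vertices
// (one row per corner, grouped in threes).
// [[Rcpp::export]]
List cpp_mesh(NumericVector field, NumericVector spacing,
              double level = 0.5) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0.0;
    return field[i + nx * (j + ny * k)];
  };
  MeshAcc acc;
  // cells span voxel centres (i..i+1, ...) over the padded grid [-1, n]
  for (int k = -1; k < nz; ++k) {
    for (int j = -1; j < ny; ++j) {
      for (int i = -1; i < nx; ++i) {
        double val[8];
        bool any_in = false, all_in = true;
        for (int c = 0; c < 8; ++c) {
          double v = at(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          val[c] = v;
          any_in |= (v > level);
          all_in &= (v > level);
        }
        if (!any_in || all_in) continue;
        V3 pos[8];
        for (int c = 0; c < 8; ++c) {
          pos[c] = V3{(i + (c & 1) + 0.5) * sx,
                      (j + ((c >> 1) & 1) + 0.5) * sy,
                      (k + ((c >> 2) & 1) + 0.5) * sz};
        }
        for (int t = 0; t < 6; ++t) {
          V3 p[4];
          double v[4];
          for (int q = 0; q < 4; ++q) {
            p[q] = pos[TETS[t][q]];
            v[q] = val[TETS[t][q]];
          }
          acc.tet(p, v, level);
        }
      }
    }
  }
  int ntri = acc.verts.size() / 9;
  NumericMatrix verts(ntri * 3, 3);
  for (int r = 0; r < ntri * 3; ++r) {
    verts(r, 0) = acc.verts[3 * r];
    verts(r, 1) = acc.verts[3 * r + 1];
    verts(r, 2) = acc.verts[3 * r + 2];
  }
  return List::create(
    _["area"] = acc.area,
    _["volume"] = acc.vol6 / 6.0,
    _["vertices"] = verts
  );
}

// Separable Gaussian smoothing of a 3D array (truncated at 3 sigma),
// zero-padded boundaries, kernel normalized to sum 1.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector field, double sigma) {
  IntegerVector dim = field.attr("dim");
  int n[3] = {dim[0], dim[1], dim[2]};
  int r = (int)std::ceil(3 * sigma);
  std::vector<double> k(2 * r + 1);
  double tot = 0;
  for (int d = -r; d <= r; ++d) {
    k[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    tot += k[d + r];
  }
  for (double &w : k) w /= tot;
  NumericVector cur = clone(field);
  int stride[3] = {1, n[0], n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    NumericVector nxt(cur.size());
    int len = n[ax];
    for (int z = 0; z < n[2]; ++z) {
      for (int y = 0; y < n[1]; ++y) {
        for (int x = 0; x < n[0]; ++x) {
          int pos[3] = {x, y, z};
          int base = x + n[0] * (y + n[1] * z);
          double acc = 0;
          for (int d = -r; d <= r; ++d) {
            int q = pos[ax] + d;
            if (q < 0 || q >= len) continue;
            acc += k[d + r] * cur[base + d * stride[ax]];
          }
          nxt[base] = acc;
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Boundary voxels (< 6 face neighbours) and exact maximum diameters of the
// voxel union. For axis-aligned boxes the largest corner-to-corner distance
// between two voxels is sqrt(sum_axis (|dc| + s)^2) with dc the centre
// difference, so no corner set needs materializing. Returns
// (max3d, slice, column, row): the in-plane diameters fix the 3rd, 2nd and
// 1st axis respectively.
// [[Rcpp::export]]
NumericVector cpp_diameters(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double s[3] = {spacing[0], spacing[1], spacing[2]};
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return mask[i + nx * (j + ny * k)] != 0;
  };
  std::vector<int> bi, bj, bk;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        int nb = at(i - 1, j, k) + at(i + 1, j, k) + at(i, j - 1, k) +
                 at(i, j + 1, k) + at(i, j, k - 1) + at(i, j, k + 1);
        if (nb < 6) {
          bi.push_back(i);
          bj.push_back(j);
          bk.push_back(k);
        }
      }
    }
  }
  int n = bi.size();
  double best3 = 0, bslice = 0, bcol = 0, brow = 0;
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      double dx = std::abs((double)(bi[a] - bi[b])) * s[0] + s[0];
      double dy = std::abs((double)(bj[a] - bj[b])) * s[1] + s[1];
      double dz = std::abs((double)(bk[a] - bk[b])) * s[2] + s[2];
      double d3 = dx * dx + dy * dy + dz * dz;
      if (d3 > best3) best3 = d3;
      if (bk[a] == bk[b] && dx * dx + dy * dy > bslice)
        bslice = dx * dx + dy * dy;
      if (bj[a] == bj[b] && dx * dx + dz * dz > bcol)
        bcol = dx * dx + dz * dz;
      if (bi[a] == bi[b] && dy * dy + dz * dz > brow)
        brow = dy * dy + dz * dz;
    }
  }
  return NumericVector::create(std::sqrt(best3), std::sqrt(bslice),
                               std::sqrt(bcol), std::sqrt(brow));
}
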