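#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Texture-matrix kernels. Input is always a 3D integer array over the ROI
// bounding box with gray levels 1..ng inside the ROI and 0 outside.

static const int DIR[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, -1, 1}, {1, 1, -1}, {-1, 1, 1}
};

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Symmetric gray-level co-occurrence counts at distance 1 for the 13 unique
// 3D directions. Returns a ng x ng x 13 array of pair counts (each unordered
// pair counted once per direction; symmetrized by the caller).
// [[Rcpp::export]]
IntegerVector cpp_glcm_counts(IntegerVector bins, int ng) {
  IntegerVector dim = bins.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR[d][0], dy = DIR[d][1], dz = DIR[d][2];
    for (int k = 0; k < nz; ++k) {
      int k2 = k + dz;
      if (k2 < 0 || k2 >= nz) continue;
      for (int j = 0; j < ny; ++j) {
        int j2 = j + dy;
        if (j2 < 0 || j2 >= ny) continue;
        for (int i = 0; i < nx; ++i) {
          int i2 = i + dx;
          if (i2 < 0 || i2 >= nx) continue;
          int a = bins[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          int b = bins[idx3(i2, j2, k2, nx, ny)];
          if (b == 0) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Gray-level run-length counts per direction: maximal straight runs of equal
// gray level; voxels outside the ROI break runs. Returns ng x maxlen x 13.
// [[Rcpp::export]]
IntegerVector cpp_glrlm_counts(IntegerVector bins, int ng) {
  IntegerVector dim = bins.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  IntegerVector out(ng * lmax * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR[d][0], dy = DIR[d][1], dz = DIR[d][2];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int g = bins[idx3(i, j, k, nx, ny)];
          if (g == 0) continue;
          // run start: predecessor along -d is outside grid/ROI or differs
          int ip = i - dx, jp = j - dy, kp = k - dz;
          bool start = ip < 0 || ip >= nx || jp < 0 || jp >= ny ||
                       kp < 0 || kp >= nz ||
                       bins[idx3(ip, jp, kp, nx, ny)] != g;
          if (!start) continue;
          int len = 1;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny && k2 >= 0 &&
                 k2 < nz && bins[idx3(i2, j2, k2, nx, ny)] == g) {
            ++len;
            i2 += dx; j2 += dy; k2 += dz;
          }
          out[(g - 1) + ng * (len - 1) + ng * lmax * d] += 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  return out;
}

// Gray-level size-zone list: 26-connected components of equal gray level.
// Returns a 2-column matrix (gray level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector bins, int ng) {
  IntegerVector dim = bins.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  for (int v0 = 0; v0 < n; ++v0) {
    int g = bins[v0];
    if (g == 0 || seen[v0]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(v0);
    seen[v0] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int k2 = k + dk;
        if (k2 < 0 || k2 >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j2 = j + dj;
          if (j2 < 0 || j2 >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int i2 = i + di;
            if (i2 < 0 || i2 >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            int w = idx3(i2, j2, k2, nx, ny);
            if (!seen[w] && bins[w] == g) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
        }
      }
    }
    zl.push_back(g);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}

// Gray-level dependence counts: for each ROI voxel, the number of
// 26-neighbours inside the ROI with identical gray level (tolerance 0).
// Matrix indexed by (gray level, dependence size j = count + 1), j in 1..27.
// [[Rcpp::export]]
IntegerMatrix cpp_gldm_counts(IntegerVector bins, int ng) {
  IntegerVector dim = bins.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int g = bins[idx3(i, j, k, nx, ny)];
        if (g == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int k2 = k + dk;
          if (k2 < 0 || k2 >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int j2 = j + dj;
            if (j2 < 0 || j2 >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              int i2 = i + di;
              if (i2 < 0 || i2 >= nx) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (bins[idx3(i2, j2, k2, nx, ny)] == g) ++dep;
            }
          }
        }
        out(g - 1, dep) += 1;
      }
    }
  }
  return out;
}

// Largest pairwise Euclidean distance between points (rows).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  int n = pts.nrow(), p = pts.ncol();
  double best = 0.0;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        double u = pts(a, c) - pts(b, c);
        d += u * u;
      }
      if (d > best) best = d;
    }
  }
  return std::sqrt(best);
}

// GLCM features (catalogue order, 22 values) computed from the raw
// per-direction count stack: symmetrize, normalize, per-direction features,
// averaged over directions with at least one pair. Returns all NaN when no
// direction has pairs (caller applies the degenerate convention).
// [[Rcpp::export]]
NumericVector cpp_glcm_feats(IntegerVector counts, int ng) {
  NumericVector out(22, 0.0);
  int ndir = 0;
  std::vector<double> p(ng * ng), px(ng), pdiff(ng), psum(2 * ng - 1);
  for (int d = 0; d < 13; ++d) {
    double tot = 0;
    for (int a = 0; a < ng; ++a) {
      for (int b = 0; b < ng; ++b) {
        double c = counts[a + ng * b + ng * ng * d] +
                   counts[b + ng * a + ng * ng * d];
        p[a + ng * b] = c;
        tot += c;
      }
    }
    if (tot <= 0) continue;
    ++ndir;
    for (double &q : p) q /= tot;
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);
    std::fill(psum.begin(), psum.end(), 0.0);
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b) px[a] += p[a + ng * b];
    double mu = 0;
    for (int a = 0; a < ng; ++a) mu += (a + 1) * px[a];
    double s2 = 0;
    for (int a = 0; a < ng; ++a) s2 += (a + 1 - mu) * (a + 1 - mu) * px[a];
    double ac = 0, cp = 0, cs = 0, ct = 0, con = 0, id = 0, idm = 0,
           idmn = 0, idn = 0, iv = 0, je = 0, hxy = 0, mp = 0, hxy1 = 0,
           hxy2 = 0;
    const double l2 = std::log(2.0);
    for (int a = 0; a < ng; ++a) {
      for (int b = 0; b < ng; ++b) {
        double q = p[a + ng * b];
        int i = a + 1, j = b + 1;
        pdiff[std::abs(i - j)] += q;
        psum[i + j - 2] += q;
        double dd = i - j, ss = i + j - 2 * mu;
        ac += (double)i * j * q;
        cp += ss * ss * ss * ss * q;
        cs += ss * ss * ss * q;
        ct += ss * ss * q;
        con += dd * dd * q;
        id += q / (1 + std::abs(dd));
        idm += q / (1 + dd * dd);
        idmn += q / (1 + dd * dd / ((double)ng * ng));
        idn += q / (1 + std::abs(dd) / ng);
        if (i != j) iv += q / (dd * dd);
        je += q * q;
        if (q > 0) hxy -= q * std::log(q) / l2;
        if (q > mp) mp = q;
        double pp = px[a] * px[b];
        if (q > 0 && pp > 0) hxy1 -= q * std::log(pp) / l2;
        if (pp > 0) hxy2 -= pp * std::log(pp) / l2;
      }
    }
    double hx = 0;
    for (int a = 0; a < ng; ++a)
      if (px[a] > 0) hx -= px[a] * std::log(px[a]) / l2;
    double da = 0, de = 0, dv = 0;
    for (int k = 0; k < ng; ++k) da += k * pdiff[k];
    for (int k = 0; k < ng; ++k) {
      if (pdiff[k] > 0) de -= pdiff[k] * std::log(pdiff[k]) / l2;
      dv += (k - da) * (k - da) * pdiff[k];
    }
    double se = 0;
    for (size_t k = 0; k < psum.size(); ++k)
      if (psum[k] > 0) se -= psum[k] * std::log(psum[k]) / l2;
    double corr = (s2 > 0) ? (ac - mu * mu) / s2 : 1.0;
    double imc1 = (hx > 0) ? (hxy - hxy1) / hx : 0.0;
    double imc2in = 1 - std::pow(2.0, -2 * (hxy2 - hxy));
    double imc2 = std::sqrt(imc2in > 0 ? imc2in : 0);
    double f[22] = {ac,  cp,   cs,   ct,   con, corr, da, de, dv, id, idm,
                    idmn, idn, imc1, imc2, iv,  mu,   je, hxy, mp, se, s2};
    for (int q = 0; q < 22; ++q) out[q] += f[q];
  }
  if (ndir == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int q = 0; q < 22; ++q) out[q] /= ndir;
  return out;
}

// GLRLM features (catalogue order, 16 values) from the per-direction
// run-length count stack, averaged over directions with runs.
// [[Rcpp::export]]
NumericVector cpp_glrlm_feats(IntegerVector counts, int ng, int np) {
  IntegerVector dims = counts.attr("dim");
  int lmax = dims[1];
  NumericVector out(16, 0.0);
  int ndir = 0;
  const double l2 = std::log(2.0);
  for (int d = 0; d < 13; ++d) {
    double nr = 0;
    for (int i = 0; i < ng; ++i)
      for (int j = 0; j < lmax; ++j) nr += counts[i + ng * j + ng * lmax * d];
    if (nr <= 0) continue;
    ++ndir;
    double mu_i = 0, mu_j = 0;
    for (int i = 0; i < ng; ++i) {
      for (int j = 0; j < lmax; ++j) {
        double q = counts[i + ng * j + ng * lmax * d] / nr;
        mu_i += (i + 1) * q;
        mu_j += (j + 1) * q;
      }
    }
    double sre = 0, lre = 0, glv = 0, rv = 0, re = 0, lgl = 0, hgl = 0,
           srl = 0, srh = 0, lrl = 0, lrh = 0, gln = 0, rln = 0;
    for (int i = 0; i < ng; ++i) {
      double rowsum = 0;
      for (int j = 0; j < lmax; ++j) {
        double c = counts[i + ng * j + ng * lmax * d];
        rowsum += c;
        if (c <= 0) continue;
        double q = c / nr;
        double gi = i + 1, rj = j + 1;
        sre += q / (rj * rj);
        lre += q * rj * rj;
        glv += (gi - mu_i) * (gi - mu_i) * q;
        rv += (rj - mu_j) * (rj - mu_j) * q;
        re -= q * std::log(q) / l2;
        lgl += q / (gi * gi);
        hgl += q * gi * gi;
        srl += q / (gi * gi * rj * rj);
        srh += q * gi * gi / (rj * rj);
        lrl += q * rj * rj / (gi * gi);
        lrh += q * gi * gi * rj * rj;
      }
      gln += rowsum * rowsum;
    }
    for (int j = 0; j < lmax; ++j) {
      double colsum = 0;
      for (int i = 0; i < ng; ++i) colsum += counts[i + ng * j + ng * lmax * d];
      rln += colsum * colsum;
    }
    double f[16] = {sre, lre, gln / nr, gln / (nr * nr), rln / nr,
                    rln / (nr * nr), nr / np, glv, rv, re, lgl, hgl,
                    srl, srh, lrl, lrh};
    for (int q = 0; q < 16; ++q) out[q] += f[q];
  }
  if (ndir == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int q = 0; q < 16; ++q) out[q] /= ndir;
  return out;
}
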