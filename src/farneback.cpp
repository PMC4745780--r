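#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense optical flow by local polynomial expansion: each neighborhood is
// approximated by f(x) = x'Ax + b'x + c under a Gaussian applicability, and
// the displacement of the quadric between two frames gives
// d = -(1/2) A^{-1} (b2 - b1), averaged over a window and refined
// iteratively over an image pyramid.

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// solve 6x6 linear system in place (Gaussian elimination, partial pivoting)
static void solve6(double G[6][6], double m[6], double out[6]) {
  double a[6][7];
  for (int i = 0; i < 6; ++i) {
    for (int j = 0; j < 6; ++j) a[i][j] = G[i][j];
    a[i][6] = m[i];
  }
  for (int c = 0; c < 6; ++c) {
    int piv = c;
    for (int r = c + 1; r < 6; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    for (int j = 0; j < 7; ++j) std::swap(a[c][j], a[piv][j]);
    double p = a[c][c];
    for (int j = c; j < 7; ++j) a[c][j] /= p;
    for (int r = 0; r < 6; ++r) {
      if (r == c) continue;
      double f = a[r][c];
      for (int j = c; j < 7; ++j) a[r][j] -= f * a[c][j];
    }
  }
  for (int i = 0; i < 6; ++i) out[i] = a[i][6];
}

struct PolyExp {
  int nr, nc;
  // planes: bx, by, axx, ayy, axy (A = [[axx, axy/2],[axy/2, ayy]])
  std::vector<double> bx, by, axx, ayy, axy;
  void init(int r, int c) {
    nr = r; nc = c;
    bx.assign(r * c, 0); by.assign(r * c, 0);
    axx.assign(r * c, 0); ayy.assign(r * c, 0); axy.assign(r * c, 0);
  }
};

// basis order: 1, x, y, x^2, y^2, xy  (x = column offset, y = row offset)
static void poly_expansion(const std::vector<double>& img, int nr, int nc,
                           int n, double sigma, PolyExp& pe) {
  pe.init(nr, nc);
  int win = 2 * n + 1;
  std::vector<double> a(win * win), B(win * win * 6);
  double G[6][6] = {{0}};
  int idx = 0;
  for (int dj = -n; dj <= n; ++dj) {
    for (int di = -n; di <= n; ++di, ++idx) {
      double x = dj, y = di;
      double w = std::exp(-(x * x + y * y) / (2.0 * sigma * sigma));
      a[idx] = w;
      double* b = &B[idx * 6];
      b[0] = 1; b[1] = x; b[2] = y; b[3] = x * x; b[4] = y * y; b[5] = x * y;
      for (int p = 0; p < 6; ++p)
        for (int q = 0; q < 6; ++q) G[p][q] += w * b[p] * b[q];
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m[6] = {0, 0, 0, 0, 0, 0};
      int idx2 = 0;
      for (int dj = -n; dj <= n; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -n; di <= n; ++di, ++idx2) {
          double f = img[reflect_idx(i + di, nr) + jj * nr];
          double wf = a[idx2] * f;
          const double* b = &B[idx2 * 6];
          for (int p = 0; p < 6; ++p) m[p] += wf * b[p];
        }
      }
      double coef[6];
      solve6(G, m, coef);
      int o = i + j * nr;
      pe.bx[o] = coef[1]; pe.by[o] = coef[2];
      pe.axx[o] = coef[3]; pe.ayy[o] = coef[4]; pe.axy[o] = coef[5];
    }
  }
}

static void box_blur(std::vector<double>& v, int nr, int nc, int k) {
  // separable box mean of width 2k+1, mirror borders
  std::vector<double> tmp(nr * nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int d = -k; d <= k; ++d) s += v[reflect_idx(i + d, nr) + j * nr];
      tmp[i + j * nr] = s / (2 * k + 1);
    }
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0;
      for (int d = -k; d <= k; ++d) s += tmp[i + reflect_idx(j + d, nc) * nr];
      v[i + j * nr] = s / (2 * k + 1);
    }
  }
}

static inline double bilin(const std::vector<double>& v, int nr, int nc,
                           double y, double x) {
  if (y < 0) y = 0;
  if (y > nr - 1) y = nr - 1;
  if (x < 0) x = 0;
  if (x > nc - 1) x = nc - 1;
  int i0 = (int)y, j0 = (int)x;
  int i1 = i0 + 1 < nr ? i0 + 1 : i0;
  int j1 = j0 + 1 < nc ? j0 + 1 : j0;
  double fy = y - i0, fx = x - j0;
  return (1 - fy) * ((1 - fx) * v[i0 + j0 * nr] + fx * v[i0 + j1 * nr]) +
         fy * ((1 - fx) * v[i1 + j0 * nr] + fx * v[i1 + j1 * nr]);
}

static void flow_update(const PolyExp& p1, const PolyExp& p2,
                        std::vector<double>& fx, std::vector<double>& fy,
                        int window) {
  int nr = p1.nr, nc = p1.nc, n = nr * nc;
  std::vector<double> m11(n), m12(n), m22(n), v1(n), v2(n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int o = i + j * nr;
      double dx = fx[o], dy = fy[o];
      double sx = j + dx, sy = i + dy;
      double a11 = 0.5 * (p1.axx[o] + bilin(p2.axx, nr, nc, sy, sx));
      double a22 = 0.5 * (p1.ayy[o] + bilin(p2.ayy, nr, nc, sy, sx));
      double a12 = 0.25 * (p1.axy[o] + bilin(p2.axy, nr, nc, sy, sx));
      double dbx = -0.5 * (bilin(p2.bx, nr, nc, sy, sx) - p1.bx[o]);
      double dby = -0.5 * (bilin(p2.by, nr, nc, sy, sx) - p1.by[o]);
      // right-hand side includes A * d0 so that solving gives total d
      double rx = dbx + a11 * dx + a12 * dy;
      double ry = dby + a12 * dx + a22 * dy;
      // normal equations for A d = r : M = A'A (A symmetric), v = A r
      m11[o] = a11 * a11 + a12 * a12;
      m12[o] = a12 * (a11 + a22);
      m22[o] = a12 * a12 + a22 * a22;
      v1[o] = a11 * rx + a12 * ry;
      v2[o] = a12 * rx + a22 * ry;
    }
  }
  int k = window / 2;
  box_blur(m11, nr, nc, k); box_blur(m12, nr, nc, k); box_blur(m22, nr, nc, k);
  box_blur(v1, nr, nc, k);  box_blur(v2, nr, nc, k);
  for (int o = 0; o < n; ++o) {
    double det = m11[o] * m22[o] - m12[o] * m12[o];
    double tr = m11[o] + m22[o];
    double eps = 1e-9 * (tr > 1e-12 ? tr * tr : 1.0) + 1e-30;
    if (std::fabs(det) < eps) det = det >= 0 ? eps : -eps;
    fx[o] = (m22[o] * v1[o] - m12[o] * v2[o]) / det;
    fy[o] = (m11[o] * v2[o] - m12[o] * v1[o]) / det;
  }
}

// 5x5 median of a field (outlier suppression between flow iterations,
// standard practice for occlusion-boundary overshoot)
static void median5(std::vector<double>& v, int nr, int nc) {
  std::vector<double> out(nr * nc);
  double buf[25];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -2; dj <= 2; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -2; di <= 2; ++di)
          buf[m++] = v[reflect_idx(i + di, nr) + jj * nr];
      }
      std::nth_element(buf, buf + 12, buf + 25);
      out[i + j * nr] = buf[12];
    }
  }
  v.swap(out);
}

static void downsample(const std::vector<double>& src, int nr, int nc,
                       std::vector<double>& dst, int& onr, int& onc) {
  // 5-tap binomial blur then decimate by 2
  static const double ker[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  std::vector<double> t1(nr * nc), t2(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int d = -2; d <= 2; ++d)
        s += ker[d + 2] * src[reflect_idx(i + d, nr) + j * nr];
      t1[i + j * nr] = s;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double s = 0;
      for (int d = -2; d <= 2; ++d)
        s += ker[d + 2] * t1[i + reflect_idx(j + d, nc) * nr];
      t2[i + j * nr] = s;
    }
  onr = (nr + 1) / 2; onc = (nc + 1) / 2;
  dst.assign(onr * onc, 0);
  for (int j = 0; j < onc; ++j)
    for (int i = 0; i < onr; ++i)
      dst[i + j * onr] = t2[std::min(2 * i, nr - 1) +
                            std::min(2 * j, nc - 1) * nr];
}

static void resize_field(const std::vector<double>& src, int snr, int snc,
                         std::vector<double>& dst, int dnr, int dnc,
                         double scale) {
  dst.assign(dnr * dnc, 0);
  double ry = dnr > 1 ? (double)(snr - 1) / (dnr - 1) : 0;
  double rx = dnc > 1 ? (double)(snc - 1) / (dnc - 1) : 0;
  for (int j = 0; j < dnc; ++j)
    for (int i = 0; i < dnr; ++i)
      dst[i + j * dnr] = scale * bilin(src, snr, snc, i * ry, j * rx);
}

// [[Rcpp::export]]
List cpp_farneback(NumericMatrix a, NumericMatrix b, int levels, int window,
                   int iterations, int poly_n, double poly_sigma) {
  int nr = a.nrow(), nc = a.ncol();
  std::vector<std::vector<double> > pa, pb;
  std::vector<int> rs, cs;
  pa.push_back(std::vector<double>(a.begin(), a.end()));
  pb.push_back(std::vector<double>(b.begin(), b.end()));
  rs.push_back(nr); cs.push_back(nc);
  int minsz = 2 * poly_n + 3;
  for (int l = 1; l < levels; ++l) {
    if (rs.back() / 2 < minsz || cs.back() / 2 < minsz) break;
    std::vector<double> da, db;
    int onr, onc;
    downsample(pa.back(), rs.back(), cs.back(), da, onr, onc);
    downsample(pb.back(), rs.back(), cs.back(), db, onr, onc);
    pa.push_back(da); pb.push_back(db);
    rs.push_back(onr); cs.push_back(onc);
  }
  int nlev = (int)pa.size();
  std::vector<double> fx, fy;
  for (int l = nlev - 1; l >= 0; --l) {
    int lr = rs[l], lc = cs[l];
    if (l == nlev - 1) {
      fx.assign(lr * lc, 0.0);
      fy.assign(lr * lc, 0.0);
    } else {
      std::vector<double> nfx, nfy;
      resize_field(fx, rs[l + 1], cs[l + 1], nfx, lr, lc, 2.0);
      resize_field(fy, rs[l + 1], cs[l + 1], nfy, lr, lc, 2.0);
      fx = nfx; fy = nfy;
    }
    PolyExp p1, p2;
    poly_expansion(pa[l], lr, lc, poly_n, poly_sigma, p1);
    poly_expansion(pb[l], lr, lc, poly_n, poly_sigma, p2);
    for (int it = 0; it < iterations; ++it) {
      flow_update(p1, p2, fx, fy, window);
      median5(fx, lr, lc);
      median5(fy, lr, lc);
    }
  }
  NumericMatrix ox(nr, nc), oy(nr, nc);
  std::copy(fx.begin(), fx.end(), ox.begin());
  std::copy(fy.begin(), fy.end(), oy.begin());
  return List::create(Named("dx") = ox, Named("dy") = oy);
}
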