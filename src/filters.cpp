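#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mirror-reflection index (symmetric padding: -1 -> 0, n -> n-1).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol(), k = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -k; dj <= k; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -k; di <= k; ++di) {
          buf[m++] = img(reflect_idx(i + di, nr), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Non-local means on patch mean squared distances:
// w(p,q) = exp(-(||P_p - P_q||^2 / |P|) / h^2), output = weighted
// patch-center mean over the search window. Computed per search offset
// with a separable box sum of the squared difference image over a
// mirror-padded buffer -- numerically identical to the direct
// patch-by-patch formula, but O(search^2 * N) instead of
// O(search^2 * patch^2 * N).
// [[Rcpp::export]]
NumericMatrix cpp_nlm(NumericMatrix img, int patch, int search, double h) {
  int nr = img.nrow(), nc = img.ncol();
  int pk = patch / 2, sk = search / 2, pad = pk + sk;
  double parea = (double)(patch * patch), h2 = h * h;
  int mr = nr + 2 * pad, mc = nc + 2 * pad;
  std::vector<double> P(mr * mc);
  for (int j = 0; j < mc; ++j) {
    int jj = reflect_idx(j - pad, nc);
    for (int i = 0; i < mr; ++i)
      P[i + j * mr] = img(reflect_idx(i - pad, nr), jj);
  }
  std::vector<double> num(nr * nc, 0.0), den(nr * nc, 0.0);
  // buffers sized for patch-extended pixel block
  int br = nr + 2 * pk, bc = nc + 2 * pk;
  std::vector<double> d2(br * bc), rowsum(br * nc);
  for (int sj = -sk; sj <= sk; ++sj) {
    for (int si = -sk; si <= sk; ++si) {
      // squared difference image on the pk-extended block
      for (int j = 0; j < bc; ++j) {
        int aj = (j - pk + pad) * mr, bj = (j - pk + sj + pad) * mr;
        for (int i = 0; i < br; ++i) {
          double d = P[i - pk + pad + aj] - P[i - pk + si + pad + bj];
          d2[i + j * br] = d * d;
        }
      }
      // horizontal box sum of width patch -> rowsum (br x nc)
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < br; ++i) {
          double s = 0;
          for (int t = 0; t < patch; ++t) s += d2[i + (j + t) * br];
          rowsum[i + j * br] = s;
        }
      }
      // vertical box sum, weight, accumulate
      for (int j = 0; j < nc; ++j) {
        int qoff = (j + sj + pad) * mr;
        for (int i = 0; i < nr; ++i) {
          double s = 0;
          for (int t = 0; t < patch; ++t) s += rowsum[i + t + j * br];
          double w = std::exp(-(s / parea) / h2);
          num[i + j * nr] += w * P[i + si + pad + qoff];
          den[i + j * nr] += w;
        }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int k = 0; k < nr * nc; ++k) out[k] = num[k] / den[k];
  return out;
}

// Direct quadratic-cost non-local means used only as a cross-check oracle
// on tiny images.
// [[Rcpp::export]]
NumericMatrix cpp_nlm_direct(NumericMatrix img, int patch, int search,
                             double h) {
  int nr = img.nrow(), nc = img.ncol();
  int pk = patch / 2, sk = search / 2;
  double parea = (double)(patch * patch), h2 = h * h;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double wsum = 0.0, vsum = 0.0;
      for (int sj = -sk; sj <= sk; ++sj) {
        for (int si = -sk; si <= sk; ++si) {
          int qi = i + si, qj = j + sj;
          double dd = 0.0;
          for (int pj = -pk; pj <= pk; ++pj) {
            int aj = reflect_idx(j + pj, nc), bj = reflect_idx(qj + pj, nc);
            for (int pi = -pk; pi <= pk; ++pi) {
              double diff = img(reflect_idx(i + pi, nr), aj) -
                            img(reflect_idx(qi + pi, nr), bj);
              dd += diff * diff;
            }
          }
          double w = std::exp(-(dd / parea) / h2);
          wsum += w;
          vsum += w * img(reflect_idx(qi, nr), reflect_idx(qj, nc));
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}

// Joint spatial/range mean-shift filtering (mode seeking per pixel).
// [[Rcpp::export]]
NumericMatrix cpp_meanshift(NumericMatrix img, int spatial_r, double range_r,
                            int max_iter) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double ci = i, cj = j, cv = img(i, j);
      for (int it = 0; it < max_iter; ++it) {
        int bi = (int)std::lround(ci), bj = (int)std::lround(cj);
        double si = 0, sj = 0, sv = 0;
        int cnt = 0;
        for (int dj = -spatial_r; dj <= spatial_r; ++dj) {
          int jj = bj + dj;
          if (jj < 0 || jj >= nc) continue;
          for (int di = -spatial_r; di <= spatial_r; ++di) {
            int ii = bi + di;
            if (ii < 0 || ii >= nr) continue;
            if (di * di + dj * dj > spatial_r * spatial_r) continue;
            double v = img(ii, jj);
            if (std::fabs(v - cv) <= range_r) {
              si += ii; sj += jj; sv += v; ++cnt;
            }
          }
        }
        if (cnt == 0) break;
        double ni = si / cnt, nj = sj / cnt, nv = sv / cnt;
        double shift = std::fabs(ni - ci) + std::fabs(nj - cj) +
                       std::fabs(nv - cv);
        ci = ni; cj = nj; cv = nv;
        if (shift < 0.1) break;
      }
      out(i, j) = cv;
    }
  }
  return out;
}

// Shannon entropy (bits) of the 8-bit intensity histogram in a disc
// neighborhood of given radius; mirror borders.
// [[Rcpp::export]]
NumericMatrix cpp_entropy_filter(IntegerMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int> > offs;
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      if (di * di + dj * dj <= radius * radius)
        offs.push_back(std::make_pair(di, dj));
  int nn = (int)offs.size();
  std::vector<int> hist(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int m = 0; m < nn; ++m) {
        int v = img(reflect_idx(i + offs[m].first, nr),
                    reflect_idx(j + offs[m].second, nc));
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        hist[v]++;
      }
      double ent = 0.0;
      for (int b = 0; b < 256; ++b) {
        if (hist[b] > 0) {
          double p = (double)hist[b] / nn;
          ent -= p * std::log2(p);
        }
      }
      out(i, j) = ent;
    }
  }
  return out;
}

// Weighted local mean with an arbitrary (2k+1)x(2k+1) kernel, mirror borders.
// Kernel is passed in so R and C++ agree on the weights bit-for-bit.
// [[Rcpp::export]]
NumericMatrix cpp_weighted_local_mean(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int k = kernel.nrow() / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      long double acc = 0.0L;
      for (int dj = -k; dj <= k; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -k; di <= k; ++di) {
          acc += (long double)kernel(di + k, dj + k) *
                 (long double)img(reflect_idx(i + di, nr), jj);
        }
      }
      out(i, j) = (double)acc;
    }
  }
  return out;
}

// Connected component labeling (first-encounter order, column-major scan);
// connectivity 8 (default for foreground) or 4 (dual, for background).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbor boundary tracing (8-connected) of the component with the
// given label, with Jacob's stopping criterion. Returns Nx2 matrix of
// 0-based (row, col) vertices of the closed outer boundary.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_contour(IntegerMatrix lab, int label) {
  int nr = lab.nrow(), nc = lab.ncol();
  // first foreground pixel in row-major scan: its west neighbor is background
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab(i, j) == label) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // clockwise Moore neighborhood (image rows grow downward):
  // W, NW, N, NE, E, SE, S, SW
  const int mi[8] = { 0, -1, -1, -1, 0, 1, 1,  1};
  const int mj[8] = {-1, -1,  0,  1, 1, 1, 0, -1};
  std::vector<int> ri, rj;
  int ci = si, cj = sj;
  int back_dir = 0;  // direction from current pixel to last background (west)
  ri.push_back(ci); rj.push_back(cj);
  bool have_start_state = false;
  int start_move = -1;
  long limit = 8L * (long)nr * nc + 16;
  for (long step = 0; step < limit; ++step) {
    int found = -1, last_bg = back_dir;
    for (int t = 1; t <= 8; ++t) {
      int d = (back_dir + t) % 8;
      int ni = ci + mi[d], nj = cj + mj[d];
      if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && lab(ni, nj) == label) {
        found = d;
        break;
      }
      last_bg = d;
    }
    if (found < 0) break;  // isolated pixel
    if (ci == si && cj == sj) {
      if (!have_start_state) { start_move = found; have_start_state = true; }
      else if (found == start_move) break;  // Jacob's criterion
    }
    // background cell just before the found neighbor, as absolute offset
    int bgi = ci + mi[last_bg], bgj = cj + mj[last_bg];
    ci += mi[found]; cj += mj[found];
    ri.push_back(ci); rj.push_back(cj);
    // direction from the NEW current pixel to that background cell
    int di = bgi - ci, dj = bgj - cj;
    back_dir = 0;
    for (int d = 0; d < 8; ++d)
      if (mi[d] == di && mj[d] == dj) { back_dir = d; break; }
  }
  // drop trailing re-visits of the start pixel (contour is closed implicitly)
  while (ri.size() > 1 && ri.back() == si && rj.back() == sj) {
    ri.pop_back(); rj.pop_back();
  }
  IntegerMatrix out((int)ri.size(), 2);
  for (int m = 0; m < (int)ri.size(); ++m) { out(m,0)=ri[m]; out(m,1)=rj[m]; }
  return out;
}
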