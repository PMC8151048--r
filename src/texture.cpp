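#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grey-level texture matrix construction on 3D integer volumes.
// Convention: levels[i,j,k] in 1..ng inside the ROI, 0 outside.
// Directions are voxel offsets (di, dj, dk); callers pass the 13 unique
// 3D directions at Chebyshev distance 1 (or a subset for testing).

static inline int idx3(int i, int j, int k, int ni, int nj) {
  return i + ni * (j + nj * k);
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, int ng, IntegerMatrix dirs) {
  IntegerVector dim = levels.attr("dim");
  int ni = dim[0], nj = dim[1], nk = dim[2];
  NumericMatrix counts(ng, ng);
  for (int d = 0; d < dirs.nrow(); ++d) {
    int di = dirs(d, 0), dj = dirs(d, 1), dk = dirs(d, 2);
    for (int k = 0; k < nk; ++k) {
      for (int j = 0; j < nj; ++j) {
        for (int i = 0; i < ni; ++i) {
          int a = levels[idx3(i, j, k, ni, nj)];
          if (a == 0) continue;
          int i2 = i + di, j2 = j + dj, k2 = k + dk;
          if (i2 < 0 || i2 >= ni || j2 < 0 || j2 >= nj || k2 < 0 || k2 >= nk)
            continue;
          int b = levels[idx3(i2, j2, k2, ni, nj)];
          if (b == 0) continue;
          counts(a - 1, b - 1) += 1.0;  // symmetric: add both orientations
          counts(b - 1, a - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, int ng, IntegerMatrix dirs) {
  IntegerVector dim = levels.attr("dim");
  int ni = dim[0], nj = dim[1], nk = dim[2];
  int maxlen = std::max(ni, std::max(nj, nk));
  NumericMatrix counts(ng, maxlen);
  for (int d = 0; d < dirs.nrow(); ++d) {
    int di = dirs(d, 0), dj = dirs(d, 1), dk = dirs(d, 2);
    for (int k = 0; k < nk; ++k) {
      for (int j = 0; j < nj; ++j) {
        for (int i = 0; i < ni; ++i) {
          int a = levels[idx3(i, j, k, ni, nj)];
          if (a == 0) continue;
          // run start: predecessor out of bounds, outside ROI, or different level
          int ip = i - di, jp = j - dj, kp = k - dk;
          if (ip >= 0 && ip < ni && jp >= 0 && jp < nj && kp >= 0 && kp < nk &&
              levels[idx3(ip, jp, kp, ni, nj)] == a)
            continue;
          int len = 1;
          int ic = i + di, jc = j + dj, kc = k + dk;
          while (ic >= 0 && ic < ni && jc >= 0 && jc < nj && kc >= 0 && kc < nk &&
                 levels[idx3(ic, jc, kc, ni, nj)] == a) {
            ++len;
            ic += di; jc += dj; kc += dk;
          }
          counts(a - 1, len - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Zones: 26-connected components of equal grey level. Returns the level and
// voxel count of every zone.
// [[Rcpp::export]]
List cpp_glszm_zones(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int ni = dim[0], nj = dim[1], nk = dim[2];
  int n = ni * nj * nk;
  std::vector<int> visited(n, 0);
  std::vector<int> zone_level, zone_size;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (levels[s] == 0 || visited[s]) continue;
    int lev = levels[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    visited[s] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int i = v % ni, j = (v / ni) % nj, k = v / (ni * nj);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || i2 >= ni || j2 < 0 || j2 >= nj || k2 < 0 || k2 >= nk)
              continue;
            int w = idx3(i2, j2, k2, ni, nj);
            if (!visited[w] && levels[w] == lev) {
              visited[w] = 1;
              stack.push_back(w);
            }
          }
        }
      }
    }
    zone_level.push_back(lev);
    zone_size.push_back(size);
  }
  return List::create(_["level"] = wrap(zone_level),
                      _["size"] = wrap(zone_size));
}

// NGTDM accumulators: for each level i, n_i = number of ROI voxels of level i
// having at least one valid 26-neighbour, s_i = sum of |i - mean neighbour level|.
// [[Rcpp::export]]
List cpp_ngtdm_stats(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int ni = dim[0], nj = dim[1], nk = dim[2];
  NumericVector nvec(ng), svec(ng);
  for (int k = 0; k < nk; ++k) {
    for (int j = 0; j < nj; ++j) {
      for (int i = 0; i < ni; ++i) {
        int a = levels[idx3(i, j, k, ni, nj)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || i2 >= ni || j2 < 0 || j2 >= nj || k2 < 0 || k2 >= nk)
                continue;
              int b = levels[idx3(i2, j2, k2, ni, nj)];
              if (b == 0) continue;
              sum += b;
              ++cnt;
            }
          }
        }
        if (cnt > 0) {
          nvec[a - 1] += 1.0;
          svec[a - 1] += std::abs(a - sum / cnt);
        }
      }
    }
  }
  return List::create(_["n"] = nvec, _["s"] = svec);
}

// 26-connected component labelling of a binary volume (nonzero = foreground).
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask) {
  IntegerVector dim = mask.attr("dim");
  int ni = dim[0], nj = dim[1], nk = dim[2];
  int n = ni * nj * nk;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int i = v % ni, j = (v / ni) % nj, k = v / (ni * nj);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || i2 >= ni || j2 < 0 || j2 >= nj || k2 < 0 || k2 >= nk)
              continue;
            int w = idx3(i2, j2, k2, ni, nj);
            if (mask[w] != 0 && labels[w] == 0) {
              labels[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("n_components") = next;
  return labels;
}
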