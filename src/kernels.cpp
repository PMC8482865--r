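#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <functional>
using namespace Rcpp;

// Arrays arrive in R column-major order with dim = c(d1, d2, d3); 2D images
// are passed with d3 = 1. All loops below index as i1 + d1*(i2 + d2*i3).

static inline int reflect_idx(int i, int n) {
  // symmetric (edge-repeating) boundary: ... c b a | a b c ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable Gaussian convolution with per-axis sigma in voxel units.
// sigma[k] <= 0 skips axis k. Kernel truncated at 3 sigma, normalised,
// so a constant image is exactly preserved and the mean is conserved.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dim,
                             NumericVector sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<double> cur(img.begin(), img.end());
  std::vector<double> nxt(cur.size());
  const int strides[3] = {1, d1, d1 * d2};
  const int sizes[3] = {d1, d2, d3};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || sizes[ax] == 1) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double& v : k) v /= ksum;

    const int n = sizes[ax], stride = strides[ax];
    // iterate over all 1D lines along axis ax
    for (int i3 = 0; i3 < (ax == 2 ? 1 : d3); ++i3) {
      for (int i2 = 0; i2 < (ax == 1 ? 1 : d2); ++i2) {
        for (int i1 = 0; i1 < (ax == 0 ? 1 : d1); ++i1) {
          int base = i1 + d1 * (i2 + (size_t)d2 * i3);
          for (int p = 0; p < n; ++p) {
            double acc = 0.0;
            for (int q = -r; q <= r; ++q) {
              int pr = reflect_idx(p + q, n);
              acc += k[q + r] * cur[base + (size_t)pr * stride];
            }
            nxt[base + (size_t)p * stride] = acc;
          }
        }
      }
    }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a binary volume under 6-, 18- or
// 26-neighbour connectivity (face / face+edge / face+edge+corner).
// For single-slice input this reduces to 4- resp. 8-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t nvox = (size_t)d1 * d2 * d3;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> off1, off2, off3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off1.push_back(a); off2.push_back(b); off3.push_back(c);
      }
  const int noff = (int)off1.size();

  IntegerVector labels(nvox, 0);
  std::vector<size_t> stack;
  int next_label = 0;

  for (size_t seed = 0; seed < nvox; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int i3 = (int)(v / ((size_t)d1 * d2));
      int rem = (int)(v % ((size_t)d1 * d2));
      int i2 = rem / d1, i1 = rem % d1;
      for (int o = 0; o < noff; ++o) {
        int j1 = i1 + off1[o], j2 = i2 + off2[o], j3 = i3 + off3[o];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
          continue;
        size_t w = j1 + (size_t)d1 * (j2 + (size_t)d2 * j3);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Greedy selection of candidate points with a minimum pairwise physical
// separation, visiting candidates in the supplied order (1-based) and
// using a uniform grid of cell size min_sep for neighbour queries.
// Returns the 1-based indices of the accepted candidates.
// [[Rcpp::export]]
IntegerVector cpp_pick_separated(IntegerMatrix cand, IntegerVector ord,
                                 NumericVector vs, double min_sep,
                                 int n_wanted) {
  struct Key {
    long long v;
    bool operator==(const Key& o) const { return v == o.v; }
  };
  struct KeyHash {
    size_t operator()(const Key& k) const {
      return std::hash<long long>()(k.v);
    }
  };
  auto mk = [](long long a, long long b, long long c) {
    Key k; k.v = (a + 1048576) + ((b + 1048576) << 21) +
      ((c + 1048576) << 42);
    return k;
  };
  std::unordered_map<Key, std::vector<int>, KeyHash> grid;
  std::vector<double> px, py, pz;
  std::vector<int> acc;
  const double sep2 = min_sep * min_sep;
  for (int t = 0; t < ord.size() && (int)acc.size() < n_wanted; ++t) {
    int i = ord[t] - 1;
    double z = cand(i, 0) * vs[0], y = cand(i, 1) * vs[1],
      x = cand(i, 2) * vs[2];
    long long cz = (long long)std::floor(z / min_sep);
    long long cy = (long long)std::floor(y / min_sep);
    long long cx = (long long)std::floor(x / min_sep);
    bool ok = true;
    for (long long a = cz - 1; a <= cz + 1 && ok; ++a)
      for (long long b = cy - 1; b <= cy + 1 && ok; ++b)
        for (long long c = cx - 1; c <= cx + 1 && ok; ++c) {
          auto it = grid.find(mk(a, b, c));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double dz = pz[j] - z, dy = py[j] - y, dx = px[j] - x;
            if (dz * dz + dy * dy + dx * dx < sep2) { ok = false; break; }
          }
        }
    if (ok) {
      grid[mk(cz, cy, cx)].push_back((int)pz.size());
      pz.push_back(z); py.push_back(y); px.push_back(x);
      acc.push_back(i + 1);
    }
  }
  return wrap(acc);
}

// Binary dilation by an arbitrary offset list (columns: d1, d2, d3
// offsets). Every true voxel stamps the whole structuring element.
// [[Rcpp::export]]
LogicalVector cpp_dilate_offsets(LogicalVector mask, IntegerVector dim,
                                 IntegerMatrix off) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t nvox = (size_t)d1 * d2 * d3;
  LogicalVector out(nvox, false);
  const int noff = off.nrow();
  for (size_t v = 0; v < nvox; ++v) {
    if (!mask[v]) continue;
    int i3 = (int)(v / ((size_t)d1 * d2));
    int rem = (int)(v % ((size_t)d1 * d2));
    int i2 = rem / d1, i1 = rem % d1;
    for (int o = 0; o < noff; ++o) {
      int j1 = i1 + off(o, 0), j2 = i2 + off(o, 1), j3 = i3 + off(o, 2);
      if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
        continue;
      out[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Binary erosion by an arbitrary offset list: a voxel survives iff the
// whole structuring element fits inside the mask (out-of-bounds counts
// as background). Early exit keeps this cheap for small masks.
// [[Rcpp::export]]
LogicalVector cpp_erode_offsets(LogicalVector mask, IntegerVector dim,
                                IntegerMatrix off) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t nvox = (size_t)d1 * d2 * d3;
  LogicalVector out(nvox, false);
  const int noff = off.nrow();
  for (size_t v = 0; v < nvox; ++v) {
    if (!mask[v]) continue;
    int i3 = (int)(v / ((size_t)d1 * d2));
    int rem = (int)(v % ((size_t)d1 * d2));
    int i2 = rem / d1, i1 = rem % d1;
    bool keep = true;
    for (int o = 0; o < noff && keep; ++o) {
      int j1 = i1 + off(o, 0), j2 = i2 + off(o, 1), j3 = i3 + off(o, 2);
      if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
        keep = false;
      else if (!mask[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)])
        keep = false;
    }
    if (keep) out[v] = true;
  }
  out.attr("dim") = dim;
  return out;
}

// one majority-vote (binary median) pass over the 3^d neighbourhood of
// interface voxels (those with a differing face neighbour); ties keep
// the current value. Used as the curvature-smoothing step of the
// morphological active-contour iteration. Restricting the vote to the
// interface leaves uniform regions untouched and keeps the pass cheap.
static void majority_smooth(std::vector<unsigned char>& u,
                            std::vector<unsigned char>& tmp,
                            int d1, int d2, int d3) {
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t v0 = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
        unsigned char uv = u[v0];
        bool boundary = false;
        if (i1 > 0 && u[v0 - 1] != uv) boundary = true;
        else if (i1 + 1 < d1 && u[v0 + 1] != uv) boundary = true;
        else if (i2 > 0 && u[v0 - (size_t)d1] != uv) boundary = true;
        else if (i2 + 1 < d2 && u[v0 + (size_t)d1] != uv) boundary = true;
        else if (i3 > 0 && u[v0 - (size_t)d1 * d2] != uv) boundary = true;
        else if (i3 + 1 < d3 && u[v0 + (size_t)d1 * d2] != uv)
          boundary = true;
        if (!boundary) { tmp[v0] = uv; continue; }
        int ones = 0, tot = 0;
        for (int a = (d3 > 1 ? -1 : 0); a <= (d3 > 1 ? 1 : 0); ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              int j1 = i1 + c, j2 = i2 + b, j3 = i3 + a;
              if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 ||
                  j3 < 0 || j3 >= d3) continue;
              ++tot;
              ones += u[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)];
            }
        size_t v = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
        if (2 * ones > tot) tmp[v] = 1;
        else if (2 * ones < tot) tmp[v] = 0;
        else tmp[v] = u[v];
      }
  std::swap(u, tmp);
}

// Region-based (edge-free) morphological active contour: at each
// iteration the interface voxels flip toward the closer of the inside /
// outside region means, followed by `smoothing` majority-vote passes
// approximating curvature flow. The front moves at most one voxel per
// update plus one per smoothing pass, so growth is bounded by
// iterations * (1 + smoothing) voxels around the initial mask.
// [[Rcpp::export]]
LogicalVector cpp_morph_acwe(NumericVector img, LogicalVector init,
                             IntegerVector dim, int iterations,
                             int smoothing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t nvox = (size_t)d1 * d2 * d3;
  std::vector<unsigned char> u(nvox), nu(nvox), tmp(nvox);
  for (size_t i = 0; i < nvox; ++i) u[i] = init[i] ? 1 : 0;

  for (int it = 0; it < iterations; ++it) {
    double s1 = 0, s0 = 0;
    size_t n1 = 0, n0 = 0;
    for (size_t i = 0; i < nvox; ++i) {
      if (u[i]) { s1 += img[i]; ++n1; } else { s0 += img[i]; ++n0; }
    }
    if (n1 == 0 || n0 == 0) break;
    double c1 = s1 / n1, c0 = s0 / n0;

    nu = u;
    for (int i3 = 0; i3 < d3; ++i3)
      for (int i2 = 0; i2 < d2; ++i2)
        for (int i1 = 0; i1 < d1; ++i1) {
          size_t v = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
          unsigned char uv = u[v];
          bool interface_vox = false;
          const int da[6] = {-1, 1, 0, 0, 0, 0};
          const int db[6] = {0, 0, -1, 1, 0, 0};
          const int dc[6] = {0, 0, 0, 0, -1, 1};
          for (int o = 0; o < 6 && !interface_vox; ++o) {
            int j1 = i1 + da[o], j2 = i2 + db[o], j3 = i3 + dc[o];
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 ||
                j3 < 0 || j3 >= d3) continue;
            if (u[j1 + (size_t)d1 * (j2 + (size_t)d2 * j3)] != uv)
              interface_vox = true;
          }
          if (interface_vox) {
            double x = img[v];
            double din = (x - c1) * (x - c1), dout = (x - c0) * (x - c0);
            nu[v] = (din < dout) ? 1 : 0;
          }
        }
    std::swap(u, nu);
    for (int s = 0; s < smoothing; ++s) majority_smooth(u, tmp, d1, d2, d3);
  }

  LogicalVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = u[i] != 0;
  out.attr("dim") = dim;
  return out;
}
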