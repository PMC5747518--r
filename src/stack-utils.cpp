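#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label 26-connected components of suprathreshold voxels in an XY-T stack.
// `stack` is an integer array of dim c(ny, nx, nt); voxels with value
// strictly greater than `threshold` are foreground. Returns 1-based linear
// indices of foreground voxels and their component labels (1-based,
// consecutive).
// [[Rcpp::export(name = ".label_components")]]
List label_components(IntegerVector stack, IntegerVector dims, double threshold) {
  const int ny = dims[0], nx = dims[1], nt = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nt;
  std::vector<R_xlen_t> fg;
  std::unordered_map<R_xlen_t, int> pos;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (stack[i] != NA_INTEGER && stack[i] > threshold) {
      pos[i] = (int)fg.size();
      fg.push_back(i);
    }
  }
  const int m = (int)fg.size();
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;
  for (int i = 0; i < m; ++i) {
    const R_xlen_t idx = fg[i];
    const int t = (int)(idx / ((R_xlen_t)ny * nx));
    const R_xlen_t rem = idx % ((R_xlen_t)ny * nx);
    const int x = (int)(rem / ny);
    const int y = (int)(rem % ny);
    // forward half of the 26-neighbourhood to avoid double visits
    for (int dt = 0; dt <= 1; ++dt) {
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (dt == 0 && (dx < 0 || (dx == 0 && dy <= 0))) continue;
          const int yy = y + dy, xx = x + dx, tt = t + dt;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || tt >= nt) continue;
          const R_xlen_t j = (R_xlen_t)tt * ny * nx + (R_xlen_t)xx * ny + yy;
          auto it = pos.find(j);
          if (it != pos.end()) uf_union(parent, i, it->second);
        }
      }
    }
  }
  IntegerVector out_idx(m), out_lab(m);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < m; ++i) {
    const int root = uf_find(parent, i);
    auto it = relabel.find(root);
    int lab;
    if (it == relabel.end()) {
      lab = ++next;
      relabel[root] = lab;
    } else {
      lab = it->second;
    }
    out_idx[i] = (int)(fg[i] + 1);  // 1-based for R
    out_lab[i] = lab;
  }
  return List::create(_["index"] = out_idx, _["label"] = out_lab,
                      _["n_components"] = next);
}

// Per-pixel temporal quantile of an integer stack. `stack` has dim
// c(ny, nx, nt); returns an ny x nx matrix holding the `p` quantile
// (type 1: lower order statistic) of each pixel's time series.
// [[Rcpp::export(name = ".pixel_time_quantile")]]
NumericMatrix pixel_time_quantile(IntegerVector stack, IntegerVector dims, double p) {
  const int ny = dims[0], nx = dims[1], nt = dims[2];
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  const int k = std::min(nt - 1, std::max(0, (int)std::floor(p * nt)));
  NumericMatrix out(ny, nx);
  std::vector<int> buf(nt);
  for (R_xlen_t px = 0; px < plane; ++px) {
    for (int t = 0; t < nt; ++t) buf[t] = stack[(R_xlen_t)t * plane + px];
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    out[px] = buf[k];
  }
  return out;
}
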