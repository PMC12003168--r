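#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find labelling of a binary image, 8-connected.
// Returns labels renumbered 1..K in row-major order of each component's
// first pixel (row-major = reading order: along rows, top-left first).
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(const LogicalMatrix& bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // first pass: column-major scan is fine for equivalence building
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!bin(i, j)) continue;
      // neighbours already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int cur = 0;
      for (int q = 0; q < 4; ++q) {
        int ii = nb[q][0], jj = nb[q][1];
        if (ii < 0 || ii >= nr || jj < 0) continue;
        int l = lab(ii, jj);
        if (l == 0) continue;
        int root = uf_find(parent, l);
        if (cur == 0) cur = root;
        else if (root != cur) {
          // union
          int a = uf_find(parent, cur), b = root;
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
          cur = std::min(a, b);
        }
      }
      if (cur == 0) {
        cur = next++;
        parent.push_back(cur);
      }
      lab(i, j) = cur;
    }
  }

  // resolve + renumber by first pixel in row-major (reading) order
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int l = lab(i, j);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++k;
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) != 0) lab(i, j) = remap[uf_find(parent, lab(i, j))];
  return lab;
}

// Grayscale erosion/dilation with a non-flat structuring element given as
// offset lists (dx = row offset, dy = col offset) and heights h.
// Boundary handling: replicate (indices clamped to the image).
// erosion:  out(p) = min_o  img(p + o) - h(o)
// dilation: out(p) = max_o  img(p - o) + h(o)

// [[Rcpp::export(name = ".cpp_gray_erode")]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img, const IntegerVector& dx,
                             const IntegerVector& dy, const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int q = 0; q < K; ++q) {
        int ii = i + dx[q]; if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        int jj = j + dy[q]; if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        double v = img(ii, jj) - h[q];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gray_dilate")]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img, const IntegerVector& dx,
                              const IntegerVector& dy, const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int q = 0; q < K; ++q) {
        int ii = i - dx[q]; if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        int jj = j - dy[q]; if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        double v = img(ii, jj) + h[q];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Marker-controlled watershed on a height map (flooding from seeds in
// order of DECREASING height — pass the Euclidean distance map directly).
// seeds: integer matrix, 0 = unseeded; mask: flood domain.
// Deterministic: ties in height are broken by insertion order.
#include <queue>

struct WsNode {
  double h; long order; int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.h != b.h) return a.h < b.h;     // max-heap on height
    return a.order > b.order;             // FIFO among equal heights
  }
};

// [[Rcpp::export(name = ".cpp_seeded_watershed")]]
IntegerMatrix cpp_seeded_watershed(const NumericMatrix& height,
                                   const IntegerMatrix& seeds,
                                   const LogicalMatrix& mask) {
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({height(i, j), order++, i + j * nr});
      }
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int i = nd.idx % nr, j = nd.idx / nr;
    int l = lab(i, j);
    for (int q = 0; q < 8; ++q) {
      int ii = i + di[q], jj = j + dj[q];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      lab(ii, jj) = l;
      pq.push({height(ii, jj), order++, ii + jj * nr});
    }
  }
  return lab;
}
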