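#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- exact squared Euclidean distance transform -----------------------
// Felzenszwalb & Huttenlocher separable lower-envelope algorithm, run
// along every axis of an N-d array (column-major, R layout).

static void dt1d(std::vector<double> &f, int n, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = 1e20;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector fg, IntegerVector dims) {
  const double INF = 1e20;
  int nd = dims.size();
  R_xlen_t total = 1;
  for (int a = 0; a < nd; a++) total *= dims[a];
  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; i++) out[i] = fg[i] ? INF : 0.0;

  R_xlen_t stride = 1;
  for (int a = 0; a < nd; a++) {
    int n = dims[a];
    if (n > 1) {
      std::vector<double> f(n), d(n), z(n + 1);
      std::vector<int> v(n);
      R_xlen_t block = stride * n;
      R_xlen_t nouter = total / block;
      for (R_xlen_t outer = 0; outer < nouter; outer++) {
        for (R_xlen_t inner = 0; inner < stride; inner++) {
          R_xlen_t base = outer * block + inner;
          for (int j = 0; j < n; j++) f[j] = out[base + j * stride];
          dt1d(f, n, d, v, z);
          for (int j = 0; j < n; j++) out[base + j * stride] = d[j];
        }
      }
    }
    stride *= n;
  }
  return out;
}

// ---- neighbor offsets --------------------------------------------------

static void make_offsets(const IntegerVector &dims, bool full,
                         std::vector<std::vector<int> > &offs) {
  int nd = dims.size();
  if (!full) {
    for (int a = 0; a < nd; a++) {
      for (int s = -1; s <= 1; s += 2) {
        std::vector<int> o(nd, 0);
        o[a] = s;
        offs.push_back(o);
      }
    }
  } else {
    std::vector<int> o(nd, -1);
    while (true) {
      bool allzero = true;
      for (int a = 0; a < nd; a++)
        if (o[a] != 0) allzero = false;
      if (!allzero) offs.push_back(o);
      int a = 0;
      while (a < nd) {
        o[a]++;
        if (o[a] <= 1) break;
        o[a] = -1;
        a++;
      }
      if (a == nd) break;
    }
  }
}

static inline void idx_to_coord(R_xlen_t idx, const IntegerVector &dims,
                                std::vector<int> &c) {
  for (int a = 0; a < dims.size(); a++) {
    c[a] = (int)(idx % dims[a]);
    idx /= dims[a];
  }
}

// ---- connected components ---------------------------------------------
// BFS labeling in scan order; `full_conn` selects 8/26- vs 4/6-adjacency.

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, IntegerVector dims,
                                   bool full_conn) {
  int nd = dims.size();
  R_xlen_t total = 1;
  for (int a = 0; a < nd; a++) total *= dims[a];
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; a++) {
    strides[a] = s;
    s *= dims[a];
  }
  std::vector<std::vector<int> > offs;
  make_offsets(dims, full_conn, offs);

  IntegerVector lab(total);
  std::vector<int> c(nd), cn(nd);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < total; i++) {
    if (!fg[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      idx_to_coord(p, dims, c);
      for (size_t k = 0; k < offs.size(); k++) {
        bool ok = true;
        R_xlen_t pn = p;
        for (int a = 0; a < nd; a++) {
          int ca = c[a] + offs[k][a];
          if (ca < 0 || ca >= dims[a]) {
            ok = false;
            break;
          }
          pn += (R_xlen_t)offs[k][a] * strides[a];
        }
        if (!ok) continue;
        if (fg[pn] && lab[pn] == 0) {
          lab[pn] = next;
          q.push(pn);
        }
      }
    }
  }
  return lab;
}

// ---- seeded watershed ---------------------------------------------------
// Deterministic priority flood on a height map: flooding starts at the
// seed pixels and proceeds downhill (largest height first); face
// connectivity (4 in 2D, 6 in 3D). Ties broken by insertion order so the
// result is reproducible across runs.

struct WsItem {
  double h;
  uint64_t order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsItem &a, const WsItem &b) const {
    if (a.h != b.h) return a.h < b.h;  // max-heap on height
    return a.order > b.order;          // FIFO among ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims) {
  int nd = dims.size();
  R_xlen_t total = 1;
  for (int a = 0; a < nd; a++) total *= dims[a];
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; a++) {
    strides[a] = s;
    s *= dims[a];
  }
  std::vector<std::vector<int> > offs;
  make_offsets(dims, false, offs);

  IntegerVector lab(total);
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  uint64_t order = 0;
  for (R_xlen_t i = 0; i < total; i++) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(WsItem{height[i], order++, i});
    }
  }
  std::vector<int> c(nd);
  while (!pq.empty()) {
    WsItem it = pq.top();
    pq.pop();
    R_xlen_t p = it.idx;
    idx_to_coord(p, dims, c);
    for (size_t k = 0; k < offs.size(); k++) {
      bool ok = true;
      R_xlen_t pn = p;
      for (int a = 0; a < nd; a++) {
        int ca = c[a] + offs[k][a];
        if (ca < 0 || ca >= dims[a]) {
          ok = false;
          break;
        }
        pn += (R_xlen_t)offs[k][a] * strides[a];
      }
      if (!ok) continue;
      if (mask[pn] && lab[pn] == 0) {
        lab[pn] = lab[p];
        pq.push(WsItem{height[pn], order++, pn});
      }
    }
  }
  return lab;
}
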