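#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Degree-1 Vietoris-Rips persistence over Z/2 by boundary-matrix column
// reduction. Simplices are ordered by (diameter, dimension, lexicographic
// vertex tuple); triangle columns are reduced against edges, so pairs are
// (birth edge, death triangle). Reduced death columns are kept for every
// positive-persistence pair: their edge sets are the representative cycles.
//
// Columns are bit-packed over the edge index space and reduced with
// word-wise XOR, which keeps fill-in cheap; a sparse merge-based fallback
// handles clouds whose edge count would make the packed pool too large.

namespace {

struct EdgeRec {
  double len;
  int i, j;
  bool operator<(const EdgeRec& o) const {
    if (len != o.len) return len < o.len;
    if (i != o.i) return i < o.i;
    return j < o.j;
  }
};

struct TriRec {
  double diam;
  int a, b, c;
  bool operator<(const TriRec& o) const {
    if (diam != o.diam) return diam < o.diam;
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

struct PairOut {
  std::vector<double> births, deaths;
  std::vector<int> censored;
  std::vector<std::vector<int>> cycles;  // edge-index sets, finite pairs
};

// dense path: one uint64 pool; a stored column keeps words [0 .. pivot/64]
void reduce_dense(const std::vector<TriRec>& tris,
                  const std::vector<int>& eidx,
                  const std::vector<EdgeRec>& edges, int n,
                  PairOut& out) {
  const int m = (int)edges.size();
  const int W = m / 64 + 1;
  std::vector<int> owner(m, -1);
  std::vector<size_t> col_off;       // offset of column c in pool
  std::vector<int> col_words;        // words stored for column c
  std::vector<uint64_t> pool;
  std::vector<uint64_t> buf(W);

  auto top_bit = [&](int hi_word) -> int {
    for (int w = hi_word; w >= 0; --w)
      if (buf[w]) return w * 64 + 63 - __builtin_clzll(buf[w]);
    return -1;
  };

  for (const TriRec& tr : tris) {
    int e1 = eidx[(size_t)tr.a * n + tr.b];
    int e2 = eidx[(size_t)tr.a * n + tr.c];
    int e3 = eidx[(size_t)tr.b * n + tr.c];
    int hi = std::max(e1, std::max(e2, e3));
    int hw = hi / 64;
    std::fill(buf.begin(), buf.begin() + hw + 1, 0ULL);
    buf[e1 / 64] ^= 1ULL << (e1 % 64);
    buf[e2 / 64] ^= 1ULL << (e2 % 64);
    buf[e3 / 64] ^= 1ULL << (e3 % 64);

    int p = top_bit(hw);
    while (p >= 0 && owner[p] >= 0) {
      int o = owner[p];
      const uint64_t* oc = &pool[col_off[o]];
      for (int w = 0; w < col_words[o]; ++w) buf[w] ^= oc[w];
      p = top_bit(p / 64);
    }
    if (p < 0) continue;

    int id = (int)col_off.size();
    owner[p] = id;
    int nw = p / 64 + 1;
    col_off.push_back(pool.size());
    col_words.push_back(nw);
    pool.insert(pool.end(), buf.begin(), buf.begin() + nw);

    double birth = edges[p].len, death = tr.diam;
    if (death > birth) {
      out.births.push_back(birth);
      out.deaths.push_back(death);
      out.censored.push_back(0);
      std::vector<int> cyc;
      for (int w = 0; w < nw; ++w) {
        uint64_t word = buf[w];
        while (word) {
          int b = __builtin_ctzll(word);
          cyc.push_back(w * 64 + b);
          word &= word - 1;
        }
      }
      out.cycles.push_back(std::move(cyc));
    }
  }

  // tell the caller which pivots got paired (sentinel entry, popped there)
  std::vector<int> paired;
  for (int t = 0; t < m; ++t) if (owner[t] >= 0) paired.push_back(t);
  out.cycles.push_back(std::move(paired));  // sentinel, popped by caller
}

// sparse merge-based fallback for very large edge counts
void reduce_sparse(const std::vector<TriRec>& tris,
                   const std::vector<int>& eidx,
                   const std::vector<EdgeRec>& edges, int n,
                   PairOut& out) {
  const int m = (int)edges.size();
  std::vector<int> owner(m, -1);
  std::vector<std::vector<int>> cols;
  std::vector<int> col, tmp;

  for (const TriRec& tr : tris) {
    col.clear();
    col.push_back(eidx[(size_t)tr.a * n + tr.b]);
    col.push_back(eidx[(size_t)tr.a * n + tr.c]);
    col.push_back(eidx[(size_t)tr.b * n + tr.c]);
    std::sort(col.begin(), col.end());

    while (!col.empty()) {
      int p = col.back();
      int o = owner[p];
      if (o < 0) break;
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    cols[o].begin(), cols[o].end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (col.empty()) continue;

    int p = col.back();
    int id = (int)cols.size();
    owner[p] = id;
    cols.push_back(col);
    double birth = edges[p].len, death = tr.diam;
    if (death > birth) {
      out.births.push_back(birth);
      out.deaths.push_back(death);
      out.censored.push_back(0);
      out.cycles.push_back(col);
    }
  }
  std::vector<int> paired;
  for (int t = 0; t < m; ++t) if (owner[t] >= 0) paired.push_back(t);
  out.cycles.push_back(std::move(paired));  // sentinel, popped by caller
}

}  // namespace

// [[Rcpp::export]]
List rips_h1_cpp(NumericMatrix pts, double threshold) {
  const int n = pts.nrow();
  PairOut out;

  if (n < 3) {
    return List::create(_["birth"] = out.births, _["death"] = out.deaths,
                        _["censored"] = out.censored, _["cycles"] = List(0));
  }

  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      D[(size_t)i * n + j] = d;
      D[(size_t)j * n + i] = d;
    }
  }

  std::vector<EdgeRec> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D[(size_t)i * n + j] <= threshold)
        edges.push_back({D[(size_t)i * n + j], i, j});
  std::sort(edges.begin(), edges.end());
  const int m = (int)edges.size();

  std::vector<int> eidx((size_t)n * n, -1);
  for (int t = 0; t < m; ++t) {
    eidx[(size_t)edges[t].i * n + edges[t].j] = t;
    eidx[(size_t)edges[t].j * n + edges[t].i] = t;
  }

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::vector<char> creator(m, 0);
  for (int t = 0; t < m; ++t) {
    int a = uf_find(parent, edges[t].i), b = uf_find(parent, edges[t].j);
    if (a == b) creator[t] = 1; else parent[a] = b;
  }

  std::vector<TriRec> tris;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = D[(size_t)i * n + j];
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double dik = D[(size_t)i * n + k], djk = D[(size_t)j * n + k];
        if (dik > threshold || djk > threshold) continue;
        double diam = std::max(dij, std::max(dik, djk));
        tris.push_back({diam, i, j, k});
      }
    }
  }
  std::sort(tris.begin(), tris.end());

  // dense pool needs roughly m^2/16 bytes; fall back to sparse merging
  // beyond ~60k edges (~225 MB)
  if (m <= 60000) reduce_dense(tris, eidx, edges, n, out);
  else reduce_sparse(tris, eidx, edges, n, out);

  std::vector<int> paired = std::move(out.cycles.back());
  out.cycles.pop_back();
  std::vector<char> has_pair(m, 0);
  for (int t : paired) has_pair[t] = 1;
  for (int t = 0; t < m; ++t) {
    if (creator[t] && !has_pair[t] && threshold > edges[t].len) {
      out.births.push_back(edges[t].len);
      out.deaths.push_back(threshold);
      out.censored.push_back(1);
      out.cycles.push_back(std::vector<int>());
    }
  }

  List cycles(out.births.size());
  for (size_t q = 0; q < out.births.size(); ++q) {
    if (out.censored[q]) { cycles[q] = R_NilValue; continue; }
    const std::vector<int>& cyc = out.cycles[q];
    IntegerMatrix em((int)cyc.size(), 2);
    for (size_t r = 0; r < cyc.size(); ++r) {
      em(r, 0) = edges[cyc[r]].i + 1;
      em(r, 1) = edges[cyc[r]].j + 1;
    }
    cycles[q] = em;
  }

  return List::create(_["birth"] = out.births, _["death"] = out.deaths,
                      _["censored"] = out.censored, _["cycles"] = cycles);
}
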