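#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Directed flag complex enumeration by sink extension.
//
// A directed k-simplex (v0,...,vk) is extended only by vertices u lying in the
// intersection of the out-neighbourhoods of all vi; every directed simplex is
// generated exactly once, in lexicographic order of its vertex tuple (start
// vertices ascending, candidate sets kept sorted).

namespace {

struct Enumerator {
  const std::vector<std::vector<int>>& out;
  int max_dim;            // -1 = unbounded
  double budget;          // simplex-count guard
  double total;           // simplices recorded so far (dims >= 1)
  std::vector<std::vector<int>> store; // flattened tuples per dim (index = dim - 1)
  std::vector<int> simplex;

  Enumerator(const std::vector<std::vector<int>>& out_, int max_dim_, double budget_)
    : out(out_), max_dim(max_dim_), budget(budget_), total(0.0) {}

  void record() {
    int dim = (int)simplex.size() - 1;
    if ((int)store.size() < dim) store.resize(dim);
    std::vector<int>& dst = store[dim - 1];
    dst.insert(dst.end(), simplex.begin(), simplex.end());
    total += 1.0;
    if (total > budget) {
      stop("simplex budget (%.0f) exceeded while enumerating dimension %d",
           budget, dim);
    }
  }

  void extend(const std::vector<int>& cand) {
    std::vector<int> next;
    for (size_t idx = 0; idx < cand.size(); ++idx) {
      int u = cand[idx];
      simplex.push_back(u);
      record();
      int dim = (int)simplex.size() - 1;
      if (max_dim < 0 || dim < max_dim) {
        // next candidates: cand (tail not required; full cand) ∩ out[u]
        next.clear();
        const std::vector<int>& a = cand;
        const std::vector<int>& b = out[u];
        size_t i = 0, j = 0;
        while (i < a.size() && j < b.size()) {
          if (a[i] < b[j]) ++i;
          else if (a[i] > b[j]) ++j;
          else { next.push_back(a[i]); ++i; ++j; }
        }
        if (!next.empty()) extend(next);
      }
      simplex.pop_back();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".flag_complex_cpp")]]
List flag_complex_cpp(int n, List out_nbrs, int max_dim, double budget) {
  std::vector<std::vector<int>> out(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector nb = out_nbrs[v];
    out[v].assign(nb.begin(), nb.end()); // 0-based, sorted
  }
  Enumerator en(out, max_dim, budget);
  if (max_dim != 0) {
    for (int v = 0; v < n; ++v) {
      en.simplex.assign(1, v);
      if (!out[v].empty()) en.extend(out[v]);
    }
  }
  List res(en.store.size());
  for (size_t d = 0; d < en.store.size(); ++d) {
    const std::vector<int>& flat = en.store[d];
    int width = (int)d + 2;            // vertices per simplex of dimension d+1
    int m = (int)(flat.size() / width);
    IntegerMatrix mat(m, width);
    for (int r = 0; r < m; ++r)
      for (int c = 0; c < width; ++c)
        mat(r, c) = flat[(size_t)r * width + c];
    res[d] = mat;
  }
  return res;
}

// Rank of a binary matrix over GF(2), given as 0-based triplet indices.
// Column-reduction Gaussian elimination on bit-packed columns.
// [[Rcpp::export(name = ".gf2_rank_cpp")]]
int gf2_rank_cpp(IntegerVector ri, IntegerVector ci, int nrow, int ncol) {
  if (nrow == 0 || ncol == 0 || ri.size() == 0) return 0;
  int words = (nrow + 63) / 64;
  std::vector<std::vector<uint64_t>> cols((size_t)ncol,
                                          std::vector<uint64_t>((size_t)words, 0));
  for (R_xlen_t k = 0; k < ri.size(); ++k) {
    int r = ri[k], c = ci[k];
    cols[(size_t)c][(size_t)(r >> 6)] ^= (uint64_t)1 << (r & 63);
  }
  // pivot_col[r] = index into `reduced` of the column whose lowest set bit is r
  std::vector<int> pivot_col((size_t)nrow, -1);
  std::vector<std::vector<uint64_t>> reduced;
  int rank = 0;
  for (int c = 0; c < ncol; ++c) {
    std::vector<uint64_t>& x = cols[(size_t)c];
    for (;;) {
      int low = -1;
      for (int w = 0; w < words; ++w) {
        if (x[(size_t)w]) {
          uint64_t v = x[(size_t)w];
          int b = 0;
          while (!(v & 1)) { v >>= 1; ++b; }
          low = (w << 6) + b;
          break;
        }
      }
      if (low < 0) break;           // column eliminated
      int p = pivot_col[(size_t)low];
      if (p < 0) {                  // new pivot
        pivot_col[(size_t)low] = (int)reduced.size();
        reduced.push_back(x);
        ++rank;
        break;
      }
      const std::vector<uint64_t>& y = reduced[(size_t)p];
      for (int w = 0; w < words; ++w) x[(size_t)w] ^= y[(size_t)w];
    }
  }
  return rank;
}
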