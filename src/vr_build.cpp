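#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Vietoris-Rips filtration machinery.  Simplices are stored per dimension as
// integer matrices (one simplex per row, 0-based vertex ids, strictly
// increasing) together with a birth value: the maximum pairwise dissimilarity
// among the vertices.  Within each dimension rows are sorted by
// (birth, lexicographic vertex tuple), which is the package's canonical
// filtration-preserving order; interleaving dimensions by (birth, dim, lex)
// puts every face before every coface and so yields a simplex-wise refinement.

namespace {

struct Simp {
  double birth;
  std::vector<int> v;
  bool operator<(const Simp& o) const {
    if (birth != o.birth) return birth < o.birth;
    return v < o.v;  // same dimension: lexicographic
  }
};

// key for a vertex tuple, used to look up row indices of faces
inline uint64_t tuple_key(const std::vector<int>& v, int n_vert) {
  uint64_t k = 0;
  for (int x : v) k = k * (uint64_t)(n_vert + 1) + (uint64_t)(x + 1);
  return k;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_vr_simplices")]]
List cpp_vr_simplices(NumericMatrix dist, int max_dim, double cap) {
  const int n = dist.nrow();
  List out(max_dim + 1);

  // vertices: birth 0, already sorted
  {
    IntegerMatrix vm(n, 1);
    NumericVector vb(n);
    for (int i = 0; i < n; ++i) { vm(i, 0) = i; vb[i] = 0.0; }
    out[0] = List::create(_["vertices"] = vm, _["birth"] = vb);
  }

  // edges
  std::vector<Simp> prev;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dist(i, j);
      if (d <= cap) prev.push_back(Simp{d, {i, j}});
    }
  std::sort(prev.begin(), prev.end());
  {
    IntegerMatrix em(prev.size(), 2);
    NumericVector eb(prev.size());
    for (size_t r = 0; r < prev.size(); ++r) {
      em(r, 0) = prev[r].v[0]; em(r, 1) = prev[r].v[1]; eb[r] = prev[r].birth;
    }
    if (max_dim >= 1) out[1] = List::create(_["vertices"] = em, _["birth"] = eb);
  }

  // higher dimensions: extend each simplex by a vertex larger than its last
  for (int dim = 2; dim <= max_dim; ++dim) {
    std::vector<Simp> cur;
    for (const Simp& s : prev) {
      int last = s.v.back();
      for (int w = last + 1; w < n; ++w) {
        double b = s.birth;
        bool ok = true;
        for (int u : s.v) {
          double d = dist(u, w);
          if (d > cap) { ok = false; break; }
          if (d > b) b = d;
        }
        if (ok) {
          Simp t; t.birth = b; t.v = s.v; t.v.push_back(w);
          cur.push_back(std::move(t));
        }
      }
    }
    std::sort(cur.begin(), cur.end());
    IntegerMatrix m(cur.size(), dim + 1);
    NumericVector bv(cur.size());
    for (size_t r = 0; r < cur.size(); ++r) {
      for (int c = 0; c <= dim; ++c) m(r, c) = cur[r].v[c];
      bv[r] = cur[r].birth;
    }
    out[dim] = List::create(_["vertices"] = m, _["birth"] = bv);
    prev = std::move(cur);
  }
  return out;
}

// Signed face expansion of the n-simplices in `simplices` against the row
// order given by `faces` (the (n-1)-simplices).  Returns 1-based triplets.
// [[Rcpp::export(name = ".cpp_boundary_triplets")]]
List cpp_boundary_triplets(IntegerMatrix simplices, IntegerMatrix faces, int n_vert) {
  const int ncol = simplices.nrow(), k = simplices.ncol();  // k = n + 1 vertices
  const int nrow = faces.nrow(), kf = faces.ncol();

  std::unordered_map<uint64_t, int> face_idx;
  face_idx.reserve(nrow * 2);
  {
    std::vector<int> tup(kf);
    for (int r = 0; r < nrow; ++r) {
      for (int c = 0; c < kf; ++c) tup[c] = faces(r, c);
      face_idx[tuple_key(tup, n_vert)] = r;
    }
  }

  std::vector<int> ti, tj, tx;
  ti.reserve((size_t)ncol * k); tj.reserve((size_t)ncol * k); tx.reserve((size_t)ncol * k);
  std::vector<int> tup(kf);
  for (int col = 0; col < ncol; ++col) {
    for (int omit = 0; omit < k; ++omit) {
      int p = 0;
      for (int c = 0; c < k; ++c) if (c != omit) tup[p++] = simplices(col, c);
      auto it = face_idx.find(tuple_key(tup, n_vert));
      if (it == face_idx.end())
        stop("face of simplex (column %d) missing from the face list", col + 1);
      ti.push_back(it->second + 1);
      tj.push_back(col + 1);
      tx.push_back(omit % 2 == 0 ? 1 : -1);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
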