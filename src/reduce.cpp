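#include <Rcpp.h>
#include <vector>

#include <utility>
#include "rational.h"
using namespace Rcpp;
using optcycle::Rat;

// Column reduction R = DV over exact rationals.
//
// Columns are row-sorted sparse vectors; elimination subtracts a multiple of
// the owning pivot column by a linear merge.  V is not materialized during
// reduction: each column records the operations applied to it
// (R_j = D_j - sum c_i R_{k_i}, hence V_j = e_j - sum c_i V_{k_i}); full or
// partial V columns are expanded from this log on demand.

namespace {

typedef std::vector<std::pair<int, Rat> > Col;  // sorted by row

std::vector<Col> cols_from_triplets(const IntegerVector& ti, const IntegerVector& tj,
                                    const NumericVector& tnum, const NumericVector& tden,
                                    int ncol) {
  std::vector<Col> cols(ncol);
  const int nz = ti.size();
  for (int k = 0; k < nz; ++k) {
    Rat v((int64_t)tnum[k], (int64_t)tden[k]);
    if (!v.is_zero()) cols[tj[k] - 1].push_back(std::make_pair(ti[k] - 1, v));
  }
  for (int j = 0; j < ncol; ++j)
    std::sort(cols[j].begin(), cols[j].end(),
              [](const std::pair<int, Rat>& x, const std::pair<int, Rat>& y) {
                return x.first < y.first;
              });
  return cols;
}

List cols_to_triplets(const std::vector<Col>& cols) {
  size_t nz = 0;
  for (const Col& c : cols) nz += c.size();
  IntegerVector ri(nz), rj(nz);
  NumericVector rnum(nz), rden(nz);
  size_t k = 0;
  for (size_t j = 0; j < cols.size(); ++j)
    for (const auto& e : cols[j]) {
      ri[k] = e.first + 1;
      rj[k] = (int)j + 1;
      rnum[k] = (double)e.second.num;
      rden[k] = (double)e.second.den;
      ++k;
    }
  return List::create(_["i"] = ri, _["j"] = rj, _["num"] = rnum, _["den"] = rden);
}

// dst -= c * src (merge of row-sorted columns); c = +-1 handled without
// multiplications since it dominates the reduction
void axpy_sub(Col& dst, const Rat& c, const Col& src, Col& buf) {
  buf.clear();
  buf.reserve(dst.size() + src.size());
  const bool plus1 = (c.num == 1 && c.den == 1);
  const bool minus1 = (c.num == -1 && c.den == 1);
  size_t a = 0, b = 0;
  while (a < dst.size() || b < src.size()) {
    if (b == src.size() || (a < dst.size() && dst[a].first < src[b].first)) {
      buf.push_back(dst[a++]);
    } else if (a == dst.size() || src[b].first < dst[a].first) {
      Rat v = plus1 ? -src[b].second : (minus1 ? src[b].second : -(c * src[b].second));
      buf.push_back(std::make_pair(src[b].first, v));
      ++b;
    } else {
      Rat v = plus1 ? dst[a].second - src[b].second
                    : (minus1 ? dst[a].second + src[b].second
                              : dst[a].second - c * src[b].second);
      if (!v.is_zero()) buf.push_back(std::make_pair(dst[a].first, v));
      ++a; ++b;
    }
  }
  dst.swap(buf);
}

// expand V columns from the ops log: V_j = e_j - sum c_i V_{k_i}
std::vector<Col> expand_v(const std::vector<std::vector<std::pair<int, Rat> > >& ops,
                          const std::vector<bool>& wanted_in) {
  const int ncol = (int)ops.size();
  // mark the ancestry of every wanted column
  std::vector<bool> need = wanted_in;
  for (int j = ncol - 1; j >= 0; --j)
    if (need[j])
      for (const auto& op : ops[j]) need[op.first] = true;
  std::vector<Col> V(ncol);
  Col buf;
  for (int j = 0; j < ncol; ++j) {
    if (!need[j]) continue;
    Col& vj = V[j];
    vj.push_back(std::make_pair(j, Rat(1)));
    for (const auto& op : ops[j])
      axpy_sub(vj, op.second, V[op.first], buf);
  }
  // free what was only needed as an intermediate
  for (int j = 0; j < ncol; ++j)
    if (need[j] && !wanted_in[j]) { Col tmp; V[j].swap(tmp); }
  return V;
}

std::vector<std::vector<std::pair<int, Rat> > >
ops_from_triplets(const IntegerVector& oj, const IntegerVector& ok,
                  const NumericVector& onum, const NumericVector& oden, int ncol) {
  std::vector<std::vector<std::pair<int, Rat> > > ops(ncol);
  for (int t = 0; t < oj.size(); ++t)
    ops[oj[t] - 1].push_back(std::make_pair(ok[t] - 1,
                                            Rat((int64_t)onum[t], (int64_t)oden[t])));
  return ops;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_reduce")]]
List cpp_reduce(IntegerVector ti, IntegerVector tj, NumericVector tnum,
                NumericVector tden, int nrow, int ncol, bool keep_v, bool keep_ops) {
  std::vector<Col> cols = cols_from_triplets(ti, tj, tnum, tden, ncol);
  std::vector<std::vector<std::pair<int, Rat> > > ops(ncol);
  std::vector<int> pivot_col(nrow, -1);
  IntegerVector pivots(ncol, NA_INTEGER);
  Col buf;

  for (int j = 0; j < ncol; ++j) {
    while (!cols[j].empty()) {
      int low = cols[j].back().first;
      int k = pivot_col[low];
      if (k < 0) break;
      Rat c = cols[j].back().second / cols[k].back().second;
      if (keep_ops) ops[j].push_back(std::make_pair(k, c));
      axpy_sub(cols[j], c, cols[k], buf);
    }
    if (!cols[j].empty()) {
      pivot_col[cols[j].back().first] = j;
      pivots[j] = cols[j].back().first + 1;
    }
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // ops log as triplets
  size_t nops = 0;
  for (const auto& o : ops) nops += o.size();
  IntegerVector oj(nops), ok(nops);
  NumericVector onum(nops), oden(nops);
  size_t t = 0;
  for (int j = 0; j < ncol; ++j)
    for (const auto& op : ops[j]) {
      oj[t] = j + 1; ok[t] = op.first + 1;
      onum[t] = (double)op.second.num; oden[t] = (double)op.second.den;
      ++t;
    }

  List out = List::create(_["R"] = cols_to_triplets(cols), _["pivots"] = pivots,
                          _["ops"] = List::create(_["j"] = oj, _["k"] = ok,
                                                  _["num"] = onum, _["den"] = oden));
  if (keep_v) {
    std::vector<bool> wanted(ncol, true);
    out["V"] = cols_to_triplets(expand_v(ops, wanted));
  }
  return out;
}

// Expand selected V columns from a reduction's ops log.
// [[Rcpp::export(name = ".cpp_expand_v")]]
List cpp_expand_v(IntegerVector oj, IntegerVector ok, NumericVector onum,
                  NumericVector oden, int ncol, IntegerVector wanted) {
  std::vector<std::vector<std::pair<int, Rat> > > ops =
      ops_from_triplets(oj, ok, onum, oden, ncol);
  std::vector<bool> w(ncol, false);
  for (int t = 0; t < wanted.size(); ++t) w[wanted[t] - 1] = true;
  return cols_to_triplets(expand_v(ops, w));
}

// Exact rank of a sparse rational matrix (same elimination, counting pivots).
// [[Rcpp::export(name = ".cpp_rat_rank")]]
int cpp_rat_rank(IntegerVector ti, IntegerVector tj, NumericVector tnum,
                 NumericVector tden, int nrow, int ncol) {
  std::vector<Col> cols = cols_from_triplets(ti, tj, tnum, tden, ncol);
  std::vector<int> pivot_col(nrow, -1);
  Col buf;
  int rank = 0;
  for (int j = 0; j < ncol; ++j) {
    while (!cols[j].empty()) {
      int low = cols[j].back().first;
      int k = pivot_col[low];
      if (k < 0) break;
      Rat c = cols[j].back().second / cols[k].back().second;
      axpy_sub(cols[j], c, cols[k], buf);
    }
    if (!cols[j].empty()) { pivot_col[cols[j].back().first] = j; ++rank; }
  }
  return rank;
}

// Exact sparse rational product A %*% B, both in triplet form.
// [[Rcpp::export(name = ".cpp_rat_mult")]]
List cpp_rat_mult(IntegerVector ai, IntegerVector aj, NumericVector anum, NumericVector aden,
                  int anrow, int ancol,
                  IntegerVector bi, IntegerVector bj, NumericVector bnum, NumericVector bden,
                  int bncol) {
  std::vector<Col> A = cols_from_triplets(ai, aj, anum, aden, ancol);
  std::vector<Col> B = cols_from_triplets(bi, bj, bnum, bden, bncol);
  std::vector<Col> out(bncol);
  std::vector<Rat> acc(anrow);
  std::vector<int> touched;
  for (int j = 0; j < bncol; ++j) {
    touched.clear();
    for (const auto& be : B[j]) {
      const Col& acol = A[be.first];
      for (const auto& ae : acol) {
        if (acc[ae.first].is_zero()) touched.push_back(ae.first);
        acc[ae.first] = acc[ae.first] + ae.second * be.second;
      }
    }
    std::sort(touched.begin(), touched.end());
    touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
    for (int r : touched) {
      if (!acc[r].is_zero()) out[j].push_back(std::make_pair(r, acc[r]));
      acc[r] = Rat(0);
    }
  }
  return cols_to_triplets(out);
}
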