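// Bagged CART classification trees with per-split feature subsampling.
//
// This backend exists for two reasons: the wrapper criterion inside the
// sequential forward search needs thousands of forest fits on ~40-row
// matrices per search (rf_sfs_round evaluates every candidate attribute in
// one call, avoiding per-fit R overhead), and the ensemble contract must be
// pinned exactly: bootstrap resamples of size n with replacement, majority
// vote with ties going to class 0 (normal), out-of-bag votes from trees not
// containing a row, and full determinism given an integer seed. All
// tie-breaks in split search are deterministic (lowest feature index, then
// lowest threshold).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right, pred;
};

struct SortItem {
  double v;
  int y;
};

// Grow one node over rows idx[lo, hi); returns node id.
int grow_node(const double* X, int nrow, const int* y, std::vector<int>& idx,
              int lo, int hi, const std::vector<int>& cols, int mtry,
              int min_leaf, std::mt19937& rng, Tree& T,
              std::vector<int>& colbuf, std::vector<SortItem>& sbuf) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  const int n0 = n - n1;
  const int maj = (2 * n1 > n) ? 1 : 0;  // tie -> class 0

  int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(maj);

  if (n0 == 0 || n1 == 0 || n < 2 * min_leaf) return node;

  // sample mtry distinct features (partial Fisher-Yates), deterministic
  colbuf.assign(cols.begin(), cols.end());
  const int p = (int)colbuf.size();
  const int m = std::min(mtry, p);
  for (int i = 0; i < m; ++i) {
    std::uniform_int_distribution<int> U(i, p - 1);
    std::swap(colbuf[i], colbuf[U(rng)]);
  }
  // evaluate candidates in ascending feature index for deterministic ties
  std::sort(colbuf.begin(), colbuf.begin() + m);

  const double parent = (double)n -
      ((double)n0 * n0 + (double)n1 * n1) / (double)n;  // n * gini
  double best_score = parent - 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  for (int fi = 0; fi < m; ++fi) {
    const int f = colbuf[fi];
    sbuf.clear();
    for (int i = lo; i < hi; ++i) {
      const int r = idx[i];
      sbuf.push_back({X[(size_t)f * nrow + r], y[r]});
    }
    std::sort(sbuf.begin(), sbuf.end(),
              [](const SortItem& a, const SortItem& b) { return a.v < b.v; });
    int l0 = 0, l1 = 0;
    for (int i = 0; i + 1 < n; ++i) {
      if (sbuf[i].y) ++l1; else ++l0;
      if (sbuf[i].v == sbuf[i + 1].v) continue;  // not a distinct boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const int r1 = n1 - l1, r0 = n0 - l0;
      const double score =
          (double)nl - ((double)l0 * l0 + (double)l1 * l1) / (double)nl +
          (double)nr - ((double)r0 * r0 + (double)r1 * r1) / (double)nr;
      if (score < best_score - 1e-12) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (sbuf[i].v + sbuf[i + 1].v);
      }
    }
  }
  if (best_f < 0) return node;

  // stable partition: rows with x <= thr go left
  std::vector<int> lft, rgt;
  lft.reserve(n);
  rgt.reserve(n);
  for (int i = lo; i < hi; ++i) {
    const int r = idx[i];
    if (X[(size_t)best_f * nrow + r] <= best_thr) lft.push_back(r);
    else rgt.push_back(r);
  }
  std::copy(lft.begin(), lft.end(), idx.begin() + lo);
  std::copy(rgt.begin(), rgt.end(), idx.begin() + lo + (int)lft.size());

  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  const int mid = lo + (int)lft.size();
  T.left[node] = grow_node(X, nrow, y, idx, lo, mid, cols, mtry, min_leaf,
                           rng, T, colbuf, sbuf);
  T.right[node] = grow_node(X, nrow, y, idx, mid, hi, cols, mtry, min_leaf,
                            rng, T, colbuf, sbuf);
  return node;
}

int tree_predict_row(const Tree& T, const double* X, int nrow, int r) {
  int node = 0;
  while (T.feat[node] >= 0) {
    node = (X[(size_t)T.feat[node] * nrow + r] <= T.thr[node]) ? T.left[node]
                                                               : T.right[node];
  }
  return T.pred[node];
}

Tree grow_tree(const double* X, int nrow, const int* y,
               const std::vector<int>& rows, const std::vector<int>& cols,
               int mtry, int min_leaf, std::mt19937& rng,
               std::vector<int>& colbuf, std::vector<SortItem>& sbuf) {
  std::vector<int> idx(rows);
  Tree T;
  grow_node(X, nrow, y, idx, 0, (int)idx.size(), cols, mtry, min_leaf, rng, T,
            colbuf, sbuf);
  return T;
}

List tree_to_list(const Tree& T) {
  return List::create(_["feat"] = wrap(T.feat), _["thr"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["pred"] = wrap(T.pred));
}

Tree tree_from_list(const List& L) {
  Tree T;
  T.feat = as<std::vector<int>>(L["feat"]);
  T.thr = as<std::vector<double>>(L["thr"]);
  T.left = as<std::vector<int>>(L["left"]);
  T.right = as<std::vector<int>>(L["right"]);
  T.pred = as<std::vector<int>>(L["pred"]);
  return T;
}

}  // namespace

// Fit a bagged forest. Returns the trees plus, per tree, the in-bag count of
// every training row and every tree's prediction for every training row
// (from which OOB votes and OOB-error-by-number-of-trees are assembled in R).
// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<int> cols(p);
  for (int j = 0; j < p; ++j) cols[j] = j;
  std::vector<int> colbuf;
  std::vector<SortItem> sbuf;
  sbuf.reserve(n);

  List trees(ntree);
  IntegerMatrix inbag(n, ntree), pred(n, ntree);
  std::uniform_int_distribution<int> U(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      rows[i] = U(rng);
      inbag(rows[i], t) += 1;
    }
    Tree T = grow_tree(REAL(X), n, INTEGER(y), rows, cols, mtry, min_leaf,
                       rng, colbuf, sbuf);
    for (int r = 0; r < n; ++r) pred(r, t) = tree_predict_row(T, REAL(X), n, r);
    trees[t] = tree_to_list(T);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["train_pred"] = pred);
}

// Per-tree predictions for new rows; majority voting happens in R.
// [[Rcpp::export]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    Tree T = tree_from_list(trees[t]);
    for (int r = 0; r < n; ++r) out(r, t) = tree_predict_row(T, REAL(X), n, r);
  }
  return out;
}

// One round of the sequential forward search: for every candidate column,
// the k-fold cross-validated misclassification rate of a forest trained on
// the already-selected columns plus that candidate. The fold assignment is
// supplied (fixed for the whole search) and the per-fold forest seed is
// shared across candidates so that comparisons are paired.
// [[Rcpp::export]]
NumericVector rf_sfs_round_cpp(NumericMatrix X, IntegerVector y,
                               IntegerVector sel, IntegerVector cand,
                               IntegerVector fold, int nfold, int ntree,
                               int min_leaf, int seed, int mtry_fixed) {
  const int n = X.nrow();
  const int ncand = cand.size();
  NumericVector err(ncand);

  std::vector<std::vector<int>> train_rows(nfold), test_rows(nfold);
  for (int r = 0; r < n; ++r) {
    for (int f = 0; f < nfold; ++f) {
      if (fold[r] == f) test_rows[f].push_back(r);
      else train_rows[f].push_back(r);
    }
  }
  const int k = sel.size() + 1;
  const int mtry = mtry_fixed > 0
      ? std::min(mtry_fixed, k)
      : std::max(1, (int)std::floor(std::sqrt((double)k)));

  std::vector<int> colbuf;
  std::vector<SortItem> sbuf;
  sbuf.reserve(n);

  for (int c = 0; c < ncand; ++c) {
    std::vector<int> cols(sel.begin(), sel.end());
    cols.push_back(cand[c]);
    std::sort(cols.begin(), cols.end());
    int wrong = 0;
    for (int f = 0; f < nfold; ++f) {
      std::mt19937 rng((unsigned)(seed + 7919 * f));
      const std::vector<int>& tr = train_rows[f];
      const int ntr = (int)tr.size();
      std::uniform_int_distribution<int> U(0, ntr - 1);
      std::vector<Tree> forest;
      forest.reserve(ntree);
      for (int t = 0; t < ntree; ++t) {
        std::vector<int> rows(ntr);
        for (int i = 0; i < ntr; ++i) rows[i] = tr[U(rng)];
        forest.push_back(grow_tree(REAL(X), n, INTEGER(y), rows, cols, mtry,
                                   min_leaf, rng, colbuf, sbuf));
      }
      for (int r : test_rows[f]) {
        int votes1 = 0;
        for (int t = 0; t < ntree; ++t) {
          votes1 += tree_predict_row(forest[t], REAL(X), n, r);
        }
        const int hat = (2 * votes1 > ntree) ? 1 : 0;
        if (hat != y[r]) ++wrong;
      }
    }
    err[c] = (double)wrong / (double)n;
  }
  return err;
}
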