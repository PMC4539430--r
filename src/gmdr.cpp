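#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Exhaustive GMDR search over all marker combinations of a given order.
//
// codes:  lines x markers, values in {-1, 0, +1, NA}
// scores: pooled per-line score residuals (one value per line)
// folds:  1..k fold assignment per line
// order:  combination size (1-3)
// top_k:  0 = return the accuracy of every combination (enumeration order
//         matches utils::combn); > 0 = return only the top_k combinations
//         (min-heap), used for 3-locus searches where storing everything
//         is wasteful.
//
// A cell is the joint genotype class of the combination. Training risk is
// the sum of training-fold scores in the cell: > 0 -> HIGH, < 0 -> LOW,
// empty or exactly 0 -> unclassified (excluded from accuracy). Testing
// balanced accuracy per fold = (sensitivity + specificity) / 2 where a
// test line is positive if its score > 0 and predicted positive if its
// cell is HIGH. Folds in which no test line is classifiable are dropped
// from the mean. Per fold, the combination attaining the fold's best
// testing accuracy is tracked (ties keep the earlier, i.e. lexicographic,
// combination); the count of such folds is the cross-validation
// consistency.

namespace {

struct HeapItem {
  double acc;
  int i, j, l;
};
struct HeapCmp {
  bool operator()(const HeapItem& a, const HeapItem& b) const {
    return a.acc > b.acc; // min-heap on accuracy
  }
};

const double TOL = 1e-12;

} // namespace

// [[Rcpp::export(name = ".gmdr_search")]]
List gmdr_search(IntegerMatrix codes, NumericVector scores, IntegerVector folds,
                 int order, int top_k) {
  const int n = codes.nrow(), p = codes.ncol();
  if (order < 1 || order > 3) stop("order must be 1, 2 or 3");
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, folds[i]);
  if (k < 2) stop("at least 2 folds required");

  // precompute digit per line per marker: -1 -> 0, +1 -> 1, 0 -> 2, NA -> -1
  std::vector<int> digit(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      int c = codes(i, j);
      int d;
      if (c == NA_INTEGER) d = -1;
      else if (c == -1) d = 0;
      else if (c == 1) d = 1;
      else d = 2;
      digit[static_cast<size_t>(j) * n + i] = d;
    }
  }
  std::vector<std::vector<int>> foldlines(k);
  for (int i = 0; i < n; ++i) foldlines[folds[i] - 1].push_back(i);
  const bool pos_line_any = true;
  (void)pos_line_any;

  const int ncell = (order == 1) ? 3 : (order == 2 ? 9 : 27);
  std::vector<double> tot(ncell), fsum(static_cast<size_t>(k) * ncell);
  std::vector<int> cellof(n);

  R_xlen_t ncomb;
  if (order == 1) ncomb = p;
  else if (order == 2) ncomb = (R_xlen_t)p * (p - 1) / 2;
  else ncomb = (R_xlen_t)p * (p - 1) * (p - 2) / 6;

  NumericVector all_acc;
  if (top_k <= 0) all_acc = NumericVector(ncomb);
  std::priority_queue<HeapItem, std::vector<HeapItem>, HeapCmp> heap;

  std::vector<double> best_fold_acc(k, -1.0);
  std::vector<R_xlen_t> best_fold_idx(k, -1);

  R_xlen_t idx = 0;
  int m1 = 0, m2 = 0, m3 = 0;

  auto eval_combo = [&](const int* d1, const int* d2, const int* d3) -> double {
    std::fill(tot.begin(), tot.end(), 0.0);
    std::fill(fsum.begin(), fsum.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int c = d1[i];
      if (order >= 2) {
        if (c < 0 || d2[i] < 0) { cellof[i] = -1; continue; }
        c = c * 3 + d2[i];
      }
      if (order == 3) {
        if (c < 0 || d3[i] < 0) { cellof[i] = -1; continue; }
        c = c * 3 + d3[i];
      }
      if (c < 0) { cellof[i] = -1; continue; }
      cellof[i] = c;
      tot[c] += scores[i];
      fsum[static_cast<size_t>(folds[i] - 1) * ncell + c] += scores[i];
    }
    double accsum = 0.0;
    int nf = 0;
    for (int f = 0; f < k; ++f) {
      int tp = 0, fn = 0, tn = 0, fp = 0;
      const double* fs = &fsum[static_cast<size_t>(f) * ncell];
      for (int i : foldlines[f]) {
        int c = cellof[i];
        if (c < 0) continue;
        double tr = tot[c] - fs[c];
        int pred;
        if (tr > TOL) pred = 1;
        else if (tr < -TOL) pred = 0;
        else continue; // unclassified cell
        bool pos = scores[i] > 0;
        if (pos && pred) ++tp;
        else if (pos && !pred) ++fn;
        else if (!pos && !pred) ++tn;
        else ++fp;
      }
      bool has_pos = (tp + fn) > 0, has_neg = (tn + fp) > 0;
      double acc;
      if (has_pos && has_neg) {
        acc = 0.5 * ((double)tp / (tp + fn) + (double)tn / (tn + fp));
      } else if (has_pos) {
        acc = (double)tp / (tp + fn);
      } else if (has_neg) {
        acc = (double)tn / (tn + fp);
      } else {
        continue; // fold has no classifiable test line
      }
      accsum += acc;
      ++nf;
      if (acc > best_fold_acc[f] + TOL) {
        best_fold_acc[f] = acc;
        best_fold_idx[f] = idx;
      }
    }
    return nf ? accsum / nf : NA_REAL;
  };

  auto record = [&](double acc, int i, int j, int l) {
    if (top_k <= 0) {
      all_acc[idx] = acc;
    } else if (!ISNAN(acc)) {
      if ((int)heap.size() < top_k) {
        heap.push({acc, i, j, l});
      } else if (acc > heap.top().acc) {
        heap.pop();
        heap.push({acc, i, j, l});
      }
    }
    ++idx;
  };

  if (order == 1) {
    for (m1 = 0; m1 < p; ++m1) {
      record(eval_combo(&digit[(size_t)m1 * n], nullptr, nullptr), m1, 0, 0);
    }
  } else if (order == 2) {
    for (m1 = 0; m1 < p - 1; ++m1) {
      const int* d1 = &digit[(size_t)m1 * n];
      for (m2 = m1 + 1; m2 < p; ++m2) {
        record(eval_combo(d1, &digit[(size_t)m2 * n], nullptr), m1, m2, 0);
      }
    }
  } else {
    for (m1 = 0; m1 < p - 2; ++m1) {
      const int* d1 = &digit[(size_t)m1 * n];
      for (m2 = m1 + 1; m2 < p - 1; ++m2) {
        const int* d2 = &digit[(size_t)m2 * n];
        for (m3 = m2 + 1; m3 < p; ++m3) {
          record(eval_combo(d1, d2, &digit[(size_t)m3 * n]), m1, m2, m3);
          if ((idx & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
        }
      }
    }
  }

  IntegerVector fold_best(k);
  for (int f = 0; f < k; ++f) {
    fold_best[f] = best_fold_idx[f] >= 0 ? (int)(best_fold_idx[f] + 1) : NA_INTEGER;
  }

  if (top_k <= 0) {
    return List::create(_["accuracy"] = all_acc, _["fold_best"] = fold_best,
                        _["n_combos"] = (double)ncomb);
  }
  int m = heap.size();
  IntegerMatrix combos(m, order);
  NumericVector acc(m);
  std::vector<R_xlen_t> lin(m);
  for (int t = m - 1; t >= 0; --t) {
    const HeapItem& h = heap.top();
    acc[t] = h.acc;
    combos(t, 0) = h.i + 1;
    if (order >= 2) combos(t, 1) = h.j + 1;
    if (order == 3) combos(t, 2) = h.l + 1;
    heap.pop();
  }
  return List::create(_["accuracy"] = acc, _["combos"] = combos,
                      _["fold_best"] = fold_best, _["n_combos"] = (double)ncomb);
}
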