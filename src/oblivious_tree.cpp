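#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Oblivious (symmetric) regression trees on per-sample gradient vectors.
// One (feature, threshold) pair is shared by every node of a tree level, so a
// depth-d tree is a lookup table with 2^d leaves addressed by d split bits.
//
// Features are pre-binned: codes(i, f) = number of candidate borders of
// feature f strictly below x(i, f).  Splitting at border j (1-based) sends a
// sample right iff codes(i, f) >= j, i.e. iff x > border_j.  Split quality is
// the summed squared error of gradients around leaf means, minimised greedily
// per level; minimising SSE is equivalent to maximising
// sum over child nodes of ||sum g||^2 / n.

// [[Rcpp::export]]
IntegerMatrix bin_feature_codes(NumericMatrix X, List borders) {
  const int n = X.nrow(), F = X.ncol();
  IntegerMatrix codes(n, F);
  for (int f = 0; f < F; ++f) {
    NumericVector b = borders[f];
    const int B = b.size();
    for (int i = 0; i < n; ++i) {
      const double x = X(i, f);
      int c = 0;
      while (c < B && x > b[c]) ++c;  // borders are sorted ascending
      codes(i, f) = c;
    }
  }
  return codes;
}

static double node_score(const double* sum, double cnt, int K) {
  if (cnt <= 0.0) return 0.0;
  double s2 = 0.0;
  for (int k = 0; k < K; ++k) s2 += sum[k] * sum[k];
  return s2 / cnt;
}

// [[Rcpp::export]]
List fit_oblivious_tree(IntegerMatrix codes, NumericMatrix G, int depth,
                        List borders) {
  const int n = codes.nrow(), F = codes.ncol(), K = G.ncol();
  if (G.nrow() != n) stop("codes and gradients disagree on sample count");
  if (depth < 1) stop("depth must be >= 1");

  std::vector<int> assign(n, 0);
  IntegerVector feat(depth, 0);          // 1-based; 0 marks degenerate level
  IntegerVector border_idx(depth, 0);
  NumericVector thr(depth, R_PosInf);
  NumericVector gain(depth, 0.0);
  LogicalVector degenerate(depth, false);

  // row-major copy of G so the per-sample K-vector is contiguous
  std::vector<double> Grm((size_t)n * K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Grm[(size_t)i * K + k] = G(i, k);

  int maxB = 0;
  for (int f = 0; f < F; ++f) {
    NumericVector b = borders[f];
    if (b.size() > maxB) maxB = b.size();
  }
  const int max_leaves = 1 << (depth - 1);
  std::vector<double> hsum((size_t)max_leaves * (maxB + 1) * K);
  std::vector<double> hcnt((size_t)max_leaves * (maxB + 1));

  for (int lev = 0; lev < depth; ++lev) {
    const int n_leaves = 1 << lev;

    // score of the current partition (no split): sum over leaves
    std::vector<double> leaf_sum((size_t)n_leaves * K, 0.0);
    std::vector<double> leaf_cnt(n_leaves, 0.0);
    for (int i = 0; i < n; ++i) {
      const int a = assign[i];
      leaf_cnt[a] += 1.0;
      double* s = &leaf_sum[(size_t)a * K];
      const double* g = &Grm[(size_t)i * K];
      for (int k = 0; k < K; ++k) s[k] += g[k];
    }
    double base_score = 0.0;
    for (int a = 0; a < n_leaves; ++a)
      base_score += node_score(&leaf_sum[(size_t)a * K], leaf_cnt[a], K);

    double best_score = R_NegInf;
    int best_f = -1, best_j = -1;

    for (int f = 0; f < F; ++f) {
      NumericVector b = borders[f];
      const int B = b.size();
      if (B == 0) continue;

      // histogram: per (leaf, code) gradient sums and counts
      std::fill(hsum.begin(), hsum.begin() + (size_t)n_leaves * (B + 1) * K,
                0.0);
      std::fill(hcnt.begin(), hcnt.begin() + (size_t)n_leaves * (B + 1), 0.0);
      const int* cf = &codes(0, f);
      for (int i = 0; i < n; ++i) {
        const size_t cell = (size_t)assign[i] * (B + 1) + cf[i];
        hcnt[cell] += 1.0;
        double* s = &hsum[cell * K];
        const double* g = &Grm[(size_t)i * K];
        for (int k = 0; k < K; ++k) s[k] += g[k];
      }

      // sweep borders high-to-low per leaf, accumulating the right side
      std::vector<double> score_at(B + 1, 0.0);
      std::vector<double> rsum(K);
      for (int a = 0; a < n_leaves; ++a) {
        std::fill(rsum.begin(), rsum.end(), 0.0);
        double rcnt = 0.0;
        const double tcnt = leaf_cnt[a];
        const double* tsum = &leaf_sum[(size_t)a * K];
        for (int j = B; j >= 1; --j) {
          const size_t cell = (size_t)a * (B + 1) + j;
          rcnt += hcnt[cell];
          const double* s = &hsum[cell * K];
          for (int k = 0; k < K; ++k) rsum[k] += s[k];
          // left = total - right
          double lscore = 0.0, rscore = 0.0;
          const double lcnt = tcnt - rcnt;
          if (lcnt > 0.0) {
            double s2 = 0.0;
            for (int k = 0; k < K; ++k) {
              const double v = tsum[k] - rsum[k];
              s2 += v * v;
            }
            lscore = s2 / lcnt;
          }
          rscore = node_score(rsum.data(), rcnt, K);
          score_at[j] += lscore + rscore;
        }
      }
      for (int j = 1; j <= B; ++j) {
        if (score_at[j] > best_score + 1e-12) {  // ties keep lower (f, j)
          best_score = score_at[j];
          best_f = f;
          best_j = j;
        }
      }
    }

    if (best_f < 0) {
      // no candidate borders anywhere: degenerate all-left level
      degenerate[lev] = true;
      feat[lev] = 0;
      thr[lev] = R_PosInf;
      gain[lev] = 0.0;
      continue;
    }

    NumericVector b = borders[best_f];
    feat[lev] = best_f + 1;
    border_idx[lev] = best_j;
    thr[lev] = b[best_j - 1];
    gain[lev] = best_score - base_score;
    for (int i = 0; i < n; ++i)
      if (codes(i, best_f) >= best_j) assign[i] |= (1 << lev);
  }

  // leaf values: mean gradient vector per leaf, empty leaves -> 0
  const int L = 1 << depth;
  NumericMatrix leaves(L, K);
  std::vector<double> cnt(L, 0.0);
  for (int i = 0; i < n; ++i) {
    cnt[assign[i]] += 1.0;
    for (int k = 0; k < K; ++k) leaves(assign[i], k) += G(i, k);
  }
  for (int a = 0; a < L; ++a)
    if (cnt[a] > 0.0)
      for (int k = 0; k < K; ++k) leaves(a, k) /= cnt[a];

  IntegerVector assign_out(n);
  for (int i = 0; i < n; ++i) assign_out[i] = assign[i];

  return List::create(_["feature"] = feat, _["border_index"] = border_idx,
                      _["threshold"] = thr, _["leaf_values"] = leaves,
                      _["gain"] = gain, _["degenerate"] = degenerate,
                      _["leaf_assignment"] = assign_out);
}

// [[Rcpp::export]]
NumericMatrix predict_oblivious_tree(NumericMatrix X, IntegerVector feature,
                                     NumericVector threshold,
                                     NumericMatrix leaf_values) {
  const int n = X.nrow(), d = feature.size(), K = leaf_values.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int a = 0;
    for (int l = 0; l < d; ++l) {
      const int f = feature[l];
      if (f > 0 && X(i, f - 1) > threshold[l]) a |= (1 << l);
    }
    for (int k = 0; k < K; ++k) out(i, k) = leaf_values(a, k);
  }
  return out;
}
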