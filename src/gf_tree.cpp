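#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Per-SNP regression-tree ensemble for the turnover-function engine.
//
// Response y = per-deme allele frequency, predictors X = deme x environment
// matrix. Trees are grown on bootstrap resamples of demes (unless bootstrap
// = false); at each node `mtry` candidate predictors are drawn and the best
// variance-reducing split is taken, subject to a minimum leaf size. Every
// accepted split is recorded as (predictor, threshold, impurity reduction)
// so cumulative-importance curves can be assembled along each gradient.
// Goodness-of-fit is out-of-bag R^2 (in-sample when bootstrap = false).
// All randomness comes from R's RNG.

struct SplitRec { int pred; double thr; double imp; };

class TreeGrower {
public:
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, minleaf;
  std::vector<SplitRec>& splits;
  std::vector<double>& oobPred;
  std::vector<int>& oobCnt;

  TreeGrower(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
             int minleaf_, std::vector<SplitRec>& splits_,
             std::vector<double>& oobPred_, std::vector<int>& oobCnt_)
    : X(X_), y(y_), mtry(mtry_), minleaf(minleaf_), splits(splits_),
      oobPred(oobPred_), oobCnt(oobCnt_) {}

  void grow(std::vector<int>& in, std::vector<int>& out) {
    const int n = (int) in.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : in) { sum += y[i]; sumsq += y[i] * y[i]; }
    double ssNode = sumsq - sum * sum / n;

    int bestPred = -1; double bestThr = 0.0, bestImp = 1e-12;
    if (n >= 2 * minleaf && ssNode > 1e-12) {
      const int k = X.ncol();
      // sample mtry candidate predictors without replacement
      std::vector<int> cand(k);
      std::iota(cand.begin(), cand.end(), 0);
      int m = std::min(mtry, k);
      for (int j = 0; j < m; ++j) {
        int pick = j + (int) (unif_rand() * (k - j));
        if (pick >= k) pick = k - 1;
        std::swap(cand[j], cand[pick]);
      }
      std::vector<int> ord(n);
      for (int j = 0; j < m; ++j) {
        int p = cand[j];
        std::iota(ord.begin(), ord.end(), 0);
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
          return X(in[a], p) < X(in[b], p);
        });
        double ls = 0.0, lss = 0.0;
        for (int q = 0; q < n - 1; ++q) {
          double yy = y[in[ord[q]]];
          ls += yy; lss += yy * yy;
          int nl = q + 1, nr = n - nl;
          if (nl < minleaf || nr < minleaf) continue;
          double xl = X(in[ord[q]], p), xr = X(in[ord[q + 1]], p);
          if (xr <= xl) continue;  // no gap between distinct values
          double rs = sum - ls, rss = sumsq - lss;
          double ssl = lss - ls * ls / nl;
          double ssr = rss - rs * rs / nr;
          double imp = ssNode - ssl - ssr;
          if (imp > bestImp) {
            bestImp = imp; bestPred = p; bestThr = 0.5 * (xl + xr);
          }
        }
      }
    }

    if (bestPred < 0) {  // leaf
      double mean = sum / n;
      for (int i : out) { oobPred[i] += mean; oobCnt[i] += 1; }
      return;
    }
    splits.push_back(SplitRec{bestPred, bestThr, bestImp});
    std::vector<int> inL, inR, outL, outR;
    for (int i : in)  (X(i, bestPred) <= bestThr ? inL : inR).push_back(i);
    for (int i : out) (X(i, bestPred) <= bestThr ? outL : outR).push_back(i);
    grow(inL, outL);
    grow(inR, outR);
  }
};

// [[Rcpp::export]]
List gf_fit_snp_cpp(const NumericMatrix& X, const NumericVector& y,
                    int ntree, int mtry, int minleaf, bool bootstrap) {
  const int n = X.nrow();
  if (y.size() != n) stop("X/y size mismatch");
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double ssTot = 0.0;
  for (int i = 0; i < n; ++i) ssTot += (y[i] - ybar) * (y[i] - ybar);

  std::vector<SplitRec> splits;
  std::vector<double> oobPred(n, 0.0);
  std::vector<int> oobCnt(n, 0);

  if (ssTot <= 1e-300) {  // constant response: nothing to fit
    return List::create(_["r2"] = -1.0,
                        _["splits"] = NumericMatrix(0, 3));
  }

  std::vector<int> inbag, outbag, cnt(n);
  for (int t = 0; t < ntree; ++t) {
    inbag.clear(); outbag.clear();
    if (bootstrap) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < n; ++i) {
        int pick = (int) (unif_rand() * n);
        if (pick >= n) pick = n - 1;
        cnt[pick]++;
      }
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < cnt[i]; ++c) inbag.push_back(i);
        if (cnt[i] == 0) outbag.push_back(i);
      }
    } else {
      inbag.resize(n); std::iota(inbag.begin(), inbag.end(), 0);
      outbag = inbag;  // evaluate in-sample
    }
    TreeGrower g(X, y, mtry, minleaf, splits, oobPred, oobCnt);
    g.grow(inbag, outbag);
  }

  double sse = 0.0, sst = 0.0;
  int nEval = 0;
  for (int i = 0; i < n; ++i) {
    if (oobCnt[i] > 0) {
      double pred = oobPred[i] / oobCnt[i];
      sse += (y[i] - pred) * (y[i] - pred);
      sst += (y[i] - ybar) * (y[i] - ybar);
      ++nEval;
    }
  }
  double r2 = (nEval > 1 && sst > 0) ? 1.0 - sse / sst : -1.0;

  NumericMatrix sm(splits.size(), 3);
  for (size_t s = 0; s < splits.size(); ++s) {
    sm(s, 0) = splits[s].pred + 1;  // 1-based for R
    sm(s, 1) = splits[s].thr;
    sm(s, 2) = splits[s].imp;
  }
  colnames(sm) = CharacterVector::create("predictor", "value", "improvement");
  return List::create(_["r2"] = r2, _["splits"] = sm);
}
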