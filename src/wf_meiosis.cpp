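#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis + syngamy for one Wright-Fisher generation.
//
// haps:     2N x S parental haplotype matrix (0/1). Rows 2i, 2i+1 (0-based)
//           are the two haplotypes of parent i.
// mother,
// father:   0-based parental individual indices, one per offspring.
// siteLG:   1-based linkage group per site column; columns MUST be sorted by
//           (linkage group, position).
// sitePos:  position of each site within its linkage group (0-based).
// lambdaLG: expected crossovers per linkage group per meiosis
//           (recombination rate x (sites_per_lg - 1)).
// lgLen:    map length of each linkage group in position units; crossover
//           breakpoints fall uniformly on (0, lgLen).
//
// parentCol: 0-based parent column per OUTPUT site, or -1 for a site that
//           arises by mutation this generation (ancestral allele 0
//           everywhere, then one derived copy placed in mutHapRow).
// mutHapRow: 0-based offspring haplotype row receiving the new mutation
//           (-1 for inherited sites).
//
// Internally the matrix is transposed so each haplotype is contiguous and
// inter-crossover segments are copied en bloc. Crossover counts are Poisson
// per linkage group; linkage groups assort independently. Uses R's RNG so
// results are governed by set.seed().
//
// Returns the 2n x S_out offspring haplotype matrix (rows 2j, 2j+1 belong
// to offspring j: maternal then paternal gamete).

static void make_gamete(const std::vector<signed char>& tp, int S, int parent,
                        const std::vector<int>& lgStart,
                        const std::vector<int>& lgEnd,
                        const std::vector<double>& pos,
                        const NumericVector& lambdaLG,
                        const NumericVector& lgLen,
                        signed char* out, std::vector<double>& bp) {
  const int nLG = (int) lgStart.size();
  const signed char* hapA = &tp[(size_t)(2 * parent) * S];
  const signed char* hapB = &tp[(size_t)(2 * parent + 1) * S];
  for (int l = 0; l < nLG; ++l) {
    if (lgEnd[l] <= lgStart[l]) continue;
    int cur = (unif_rand() < 0.5) ? 0 : 1;  // independent assortment
    int nx = (int) R::rpois(lambdaLG[l]);
    int seg = lgStart[l];
    if (nx > 0) {
      bp.clear();
      for (int k = 0; k < nx; ++k) bp.push_back(R::runif(0.0, lgLen[l]));
      std::sort(bp.begin(), bp.end());
      for (double b : bp) {
        // first site strictly beyond the breakpoint
        int idx = (int) (std::upper_bound(pos.begin() + seg,
                                          pos.begin() + lgEnd[l], b) -
                         pos.begin());
        if (idx > seg) {
          const signed char* src = cur == 0 ? hapA : hapB;
          std::copy(src + seg, src + idx, out + seg);
          seg = idx;
        }
        cur = 1 - cur;
      }
    }
    const signed char* src = cur == 0 ? hapA : hapB;
    std::copy(src + seg, src + lgEnd[l], out + seg);
  }
}

// [[Rcpp::export]]
IntegerMatrix wf_meiosis_cpp(const IntegerMatrix& haps,
                             const IntegerVector& mother,
                             const IntegerVector& father,
                             const IntegerVector& siteLG,
                             const NumericVector& sitePos,
                             const NumericVector& lambdaLG,
                             const NumericVector& lgLen,
                             const IntegerVector& parentCol,
                             const IntegerVector& mutHapRow) {
  const int S = parentCol.size();  // output site count
  const int twoN = haps.nrow();
  const int n = mother.size();
  if (father.size() != n) stop("mother/father length mismatch");
  if (siteLG.size() != S || sitePos.size() != S || mutHapRow.size() != S)
    stop("site vector length mismatch");
  const int nLG = lambdaLG.size();

  // contiguous column ranges per linkage group
  std::vector<int> lgStart(nLG, -1), lgEnd(nLG, 0);
  for (int s = 0; s < S; ++s) {
    int l = siteLG[s] - 1;
    if (l < 0 || l >= nLG) stop("siteLG out of range");
    if (lgStart[l] < 0) lgStart[l] = s;
    lgEnd[l] = s + 1;
  }
  for (int l = 0; l < nLG; ++l) if (lgStart[l] < 0) { lgStart[l] = 0; lgEnd[l] = 0; }

  std::vector<double> pos(sitePos.begin(), sitePos.end());

  // transpose parents (blocked for cache locality) so haplotypes are
  // contiguous; new (mutation) sites are ancestral (0) in every parent
  std::vector<signed char> tp((size_t) twoN * S, 0);
  const int B = 64;
  for (int s0 = 0; s0 < S; s0 += B) {
    int s1 = std::min(s0 + B, S);
    for (int h0 = 0; h0 < twoN; h0 += B) {
      int h1 = std::min(h0 + B, twoN);
      for (int s = s0; s < s1; ++s) {
        int pc = parentCol[s];
        if (pc < 0) continue;
        if (pc >= haps.ncol()) stop("parentCol out of range");
        const int* col = &haps(0, pc);
        for (int h = h0; h < h1; ++h) tp[(size_t) h * S + s] = (signed char) col[h];
      }
    }
  }

  std::vector<signed char> ot((size_t) 2 * n * S);
  std::vector<double> bp;
  bp.reserve(8);
  for (int j = 0; j < n; ++j) {
    make_gamete(tp, S, mother[j], lgStart, lgEnd, pos, lambdaLG, lgLen,
                &ot[(size_t)(2 * j) * S], bp);
    make_gamete(tp, S, father[j], lgStart, lgEnd, pos, lambdaLG, lgLen,
                &ot[(size_t)(2 * j + 1) * S], bp);
  }

  // place this generation's new mutations
  for (int s = 0; s < S; ++s) {
    if (parentCol[s] < 0) {
      int h = mutHapRow[s];
      if (h < 0 || h >= 2 * n) stop("mutHapRow out of range");
      ot[(size_t) h * S + s] = 1;
    }
  }

  IntegerMatrix out(2 * n, S);
  for (int s0 = 0; s0 < S; s0 += B) {
    int s1 = std::min(s0 + B, S);
    for (int h0 = 0; h0 < 2 * n; h0 += B) {
      int h1 = std::min(h0 + B, 2 * n);
      for (int s = s0; s < s1; ++s) {
        int* col = &out(0, s);
        for (int h = h0; h < h1; ++h) col[h] = ot[(size_t) h * S + s];
      }
    }
  }
  return out;
}

// Additive phenotypes from an integer haplotype matrix: for individual i
// (haplotype rows 2i, 2i+1), P_j = sum over sites of allele * alpha_j.
// Avoids coercing the haplotype matrix to double.
// [[Rcpp::export]]
NumericMatrix hap_phenotypes_cpp(const IntegerMatrix& haps,
                                 const NumericVector& alpha1,
                                 const NumericVector& alpha2) {
  const int twoN = haps.nrow(), S = haps.ncol();
  if (alpha1.size() != S || alpha2.size() != S)
    stop("alpha length mismatch");
  const int N = twoN / 2;
  NumericMatrix P(N, 2);
  for (int s = 0; s < S; ++s) {
    double a1 = alpha1[s], a2 = alpha2[s];
    if (a1 == 0.0 && a2 == 0.0) continue;
    const int* col = &haps(0, s);
    for (int h = 0; h < twoN; ++h) {
      if (col[h]) {
        P(h >> 1, 0) += a1;
        P(h >> 1, 1) += a2;
      }
    }
  }
  return P;
}
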