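#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Banded local DP over label pairs.
//
// State S(i,j) = best score of a monotone chain of label pairs ending at
// (query label i, reference label j).  A chain may start anywhere
// (local alignment; overhangs outside the aligned span are free).
// Step cost from (i-k, j-l):
//   within the lookback band (k,l <= lookback):
//     match_bonus - (dq-dr)^2 / (2 c^2 dr) - miss*(l-1) - false*(k-1)
//   single-sided jump (k == 1, lookback < l <= max_jump, or mirrored):
//     match_bonus - jump_penalty   (no sizing term)
// Jumps let one alignment bridge a long discordant stretch (e.g. a
// repeat copy-number disagreement) so that it can be recognised as an
// internal discordance rather than silently truncating the chain.
//
// Masked query labels can be skipped but never paired; greedy secondary
// extraction masks the labels of already-reported chains.

// [[Rcpp::export]]
List dp_align_cpp(NumericVector q, NumericVector r, LogicalVector qmask,
                  double coeff, double miss, double fpen, double bonus,
                  int lookback, int max_jump, double jump_penalty) {
  const int n = q.size(), m = r.size();
  List out = List::create(_["qi"] = IntegerVector(0),
                          _["ri"] = IntegerVector(0),
                          _["score"] = NA_REAL);
  if (n < 2 || m < 2) return out;
  const double NEG = -std::numeric_limits<double>::infinity();
  const double c2 = 2.0 * coeff * coeff;
  std::vector<double> S((size_t)n * m, NEG);
  std::vector<int> fromi((size_t)n * m, -1), fromj((size_t)n * m, -1);
  // best chain of >= 2 pairs (a singleton pair is not an alignment);
  // tracked separately because S clamps a poor prefix to a fresh start
  double bestM = NEG;
  int Mi = -1, Mj = -1, Mpi = -1, Mpj = -1;

  for (int i = 0; i < n; ++i) {
    if (qmask[i]) continue;
    for (int j = 0; j < m; ++j) {
      double best = bonus;            // chain starting at (i,j)
      int bi = -1, bj = -1;
      double bestExt = NEG;           // best extension (>= 2 pairs)
      int ei2 = -1, ej2 = -1;
      int kmax = std::min(lookback, i), lmax = std::min(lookback, j);
      for (int k = 1; k <= kmax; ++k) {
        if (qmask[i - k]) continue;
        double dq = q[i] - q[i - k];
        for (int l = 1; l <= lmax; ++l) {
          double prev = S[(size_t)(i - k) * m + (j - l)];
          if (prev == NEG) continue;
          double dr = r[j] - r[j - l];
          double diff = dq - dr;
          double cand = prev + bonus - diff * diff / (c2 * dr)
                        - miss * (l - 1) - fpen * (k - 1);
          if (cand > best) { best = cand; bi = i - k; bj = j - l; }
          if (cand > bestExt) { bestExt = cand; ei2 = i - k; ej2 = j - l; }
        }
      }
      // single-sided jumps beyond the band
      if (i >= 1 && !qmask[i - 1]) {
        int ljmax = std::min(max_jump, j);
        for (int l = lookback + 1; l <= ljmax; ++l) {
          double prev = S[(size_t)(i - 1) * m + (j - l)];
          if (prev == NEG) continue;
          double cand = prev + bonus - jump_penalty;
          if (cand > best) { best = cand; bi = i - 1; bj = j - l; }
          if (cand > bestExt) { bestExt = cand; ei2 = i - 1; ej2 = j - l; }
        }
      }
      if (j >= 1) {
        int kjmax = std::min(max_jump, i);
        for (int k = lookback + 1; k <= kjmax; ++k) {
          if (qmask[i - k]) continue;
          double prev = S[(size_t)(i - k) * m + (j - 1)];
          if (prev == NEG) continue;
          double cand = prev + bonus - jump_penalty;
          if (cand > best) { best = cand; bi = i - k; bj = j - 1; }
          if (cand > bestExt) { bestExt = cand; ei2 = i - k; ej2 = j - 1; }
        }
      }
      S[(size_t)i * m + j] = best;
      fromi[(size_t)i * m + j] = bi;
      fromj[(size_t)i * m + j] = bj;
      if (bestExt > bestM) {
        bestM = bestExt; Mi = i; Mj = j; Mpi = ei2; Mpj = ej2;
      }
    }
  }
  if (Mi < 0) return out;

  std::vector<int> qi, ri;
  qi.push_back(Mi + 1); ri.push_back(Mj + 1);
  int ci = Mpi, cj = Mpj;
  while (ci >= 0) {
    qi.push_back(ci + 1);
    ri.push_back(cj + 1);
    int ni = fromi[(size_t)ci * m + cj], nj = fromj[(size_t)ci * m + cj];
    ci = ni; cj = nj;
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ri.begin(), ri.end());
  out["qi"] = wrap(qi);
  out["ri"] = wrap(ri);
  out["score"] = bestM;
  return out;
}
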