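#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Canonical pairs for folding: Watson-Crick plus G.U wobble (DNA alphabet,
// so U is represented as T throughout).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Base-pair maximization (Nussinov) with hairpin loops of at least
// `min_loop` unpaired bases. Returns a 1-based pairing table: pairs[i] is the
// partner of position i+1, or 0 when unpaired. Traceback is deterministic:
// at subproblem (i, j) a pairing of i is preferred over leaving i unpaired,
// and among optimal partners the smallest k is taken, so the structure that
// closes at the smaller 5' index wins ties.
// [[Rcpp::export]]
IntegerVector nussinov_pairs(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  IntegerVector pairs(n, 0);
  if (n == 0) return pairs;
  // M[i][j]: max pairs over seq[i..j], 0-based, flattened.
  std::vector<int> M((size_t) n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t) i * n + j]; };
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = at(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1;
        if (k - 1 >= i + 1) v += at(i + 1, k - 1);
        if (k + 1 <= j) v += at(k + 1, j);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }
  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    int target = at(i, j);
    int chosen = -1;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1;
      if (k - 1 >= i + 1) v += at(i + 1, k - 1);
      if (k + 1 <= j) v += at(k + 1, j);
      if (v == target) { chosen = k; break; }
    }
    if (chosen >= 0) {
      pairs[i] = chosen + 1;
      pairs[chosen] = i + 1;
      if (chosen - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 <= j) stack.push_back(std::make_pair(chosen + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return pairs;
}

// First reference (1-based index) containing the tag as a substring in
// either orientation with at most max_mm mismatching positions; NA if none.
// References are scanned in order; within one reference the forward
// orientation is tried before the reverse complement.
// [[Rcpp::export]]
IntegerVector hamming_substring_match(CharacterVector tags,
                                      CharacterVector tags_rc,
                                      CharacterVector refs,
                                      int max_mm) {
  const int nt = tags.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  IntegerVector out(nt, NA_INTEGER);
  for (int t = 0; t < nt; ++t) {
    std::string fwd = as<std::string>(tags[t]);
    std::string rev = as<std::string>(tags_rc[t]);
    const int w = (int) fwd.size();
    for (int r = 0; r < nr && out[t] == NA_INTEGER; ++r) {
      const std::string& ref = R[r];
      const int L = (int) ref.size();
      if (L < w) continue;
      for (int ori = 0; ori < 2 && out[t] == NA_INTEGER; ++ori) {
        const std::string& q = ori == 0 ? fwd : rev;
        for (int off = 0; off + w <= L; ++off) {
          int mm = 0;
          for (int p = 0; p < w; ++p) {
            if (q[p] != ref[off + p] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) { out[t] = r + 1; break; }
        }
      }
    }
  }
  return out;
}

// Mean Phred+33 score per quality string (NaN for empty strings).
// [[Rcpp::export]]
NumericVector phred_mean(CharacterVector qual) {
  const int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(qual[i]);
    if (q.empty()) { out[i] = R_NaN; continue; }
    double s = 0;
    for (size_t p = 0; p < q.size(); ++p) s += (double) q[p] - 33.0;
    out[i] = s / (double) q.size();
  }
  return out;
}
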