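#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Two modes:
//   fit = false : true global alignment (Needleman-Wunsch), both sequences
//                 end to end.
//   fit = true  : query aligned end to end, leading/trailing reference bases
//                 free ("glocal"/fit alignment) -- used to place an assembled
//                 flank inside a larger reference window.
// Gap of length L costs gap_open + L * gap_extend.  'N' mismatches
// everything, including 'N'.  Traceback prefers diagonal over a gap in the
// reference (query-consuming) over a gap in the query; in fit mode the
// smallest reference end offset is taken on score ties.

static const int NEG = -1000000000;

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".aln_pair_cpp")]]
List aln_pair_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend,
                  bool fit) {
  const int n = (int)query.size(), m = (int)ref.size();
  const int oe = gap_open + gap_extend, e = gap_extend;
  const size_t W = (size_t)(m + 1);
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // predecessor state per cell: 0=M, 1=X, 2=Y
  std::vector<unsigned char> pM((n + 1) * W), pX((n + 1) * W), pY((n + 1) * W);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[j] = fit ? 0 : -(gap_open + e * j);
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + e * i);
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      int s = subscore(qc, ref[j - 1], match, mismatch);
      // diagonal
      int best = M[d]; unsigned char pb = 0;
      if (X[d] > best) { best = X[d]; pb = 1; }
      if (Y[d] > best) { best = Y[d]; pb = 2; }
      M[c] = (best <= NEG / 2) ? NEG : best + s; pM[c] = pb;
      // gap in reference (consume query base)
      best = (M[u] <= NEG / 2) ? NEG : M[u] - oe; pb = 0;
      if (X[u] - e > best) { best = X[u] - e; pb = 1; }
      if (Y[u] > NEG / 2 && Y[u] - oe > best) { best = Y[u] - oe; pb = 2; }
      X[c] = best; pX[c] = pb;
      // gap in query (consume reference base)
      best = (M[l] <= NEG / 2) ? NEG : M[l] - oe; pb = 0;
      if (X[l] > NEG / 2 && X[l] - oe > best) { best = X[l] - oe; pb = 1; }
      if (Y[l] - e > best) { best = Y[l] - e; pb = 2; }
      Y[c] = best; pY[c] = pb;
    }
  }
  // terminal cell/state
  int end_j = m, state = 0, score;
  if (fit) {
    score = NEG - 1;
    for (int j = 0; j <= m; ++j) {
      const size_t c = (size_t)n * W + j;
      int s = M[c]; int st = 0;
      if (X[c] > s) { s = X[c]; st = 1; }
      if (s > score) { score = s; end_j = j; state = st; }
    }
  } else {
    const size_t c = (size_t)n * W + m;
    score = M[c]; state = 0;
    if (X[c] > score) { score = X[c]; state = 1; }
    if (Y[c] > score) { score = Y[c]; state = 2; }
  }
  // traceback
  std::string gq, gr;
  int i = n, j = end_j;
  while (true) {
    if (fit && i == 0) break;
    if (i == 0 && j == 0) break;
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char pb = pM[c];
      gq.push_back(query[i - 1]); gr.push_back(ref[j - 1]);
      --i; --j; state = pb;
    } else if (state == 1) {
      unsigned char pb = pX[c];
      gq.push_back(query[i - 1]); gr.push_back('-');
      --i; state = pb;
    } else {
      unsigned char pb = pY[c];
      gq.push_back('-'); gr.push_back(ref[j - 1]);
      --j; state = pb;
    }
  }
  std::reverse(gq.begin(), gq.end());
  std::reverse(gr.begin(), gr.end());
  return List::create(_["score"] = score,
                      _["pattern"] = gq,
                      _["subject"] = gr,
                      _["ref_start"] = j,
                      _["ref_end"] = end_j);
}

// Best ungapped suffix(a)-prefix(b) overlap of length >= min_overlap with
// identity >= min_identity.  Returns c(length, matches); c(0, 0) when none.
// [[Rcpp::export(name = ".best_overlap_cpp")]]
IntegerVector best_overlap_cpp(std::string a, std::string b,
                               int min_overlap, double min_identity) {
  const int la = (int)a.size(), lb = (int)b.size();
  int best_len = 0, best_matches = -1;
  const int maxL = std::min(la, lb);
  for (int L = maxL; L >= min_overlap; --L) {
    const int budget = (int)((1.0 - min_identity) * L + 1e-9);
    int mm = 0;
    const char *pa = a.data() + (la - L), *pb = b.data();
    for (int k = 0; k < L; ++k) {
      char ca = pa[k], cb = pb[k];
      if (ca != cb || ca == 'N') {
        if (++mm > budget) break;
      }
    }
    if (mm <= budget) {
      int matches = L - mm;
      if (matches > best_matches) { best_matches = matches; best_len = L; }
    }
  }
  if (best_len == 0) return IntegerVector::create(0, 0);
  return IntegerVector::create(best_len, best_matches);
}
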