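#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Pairwise DNA alignment kernels used by the clustering and reconstruction
// scoring code. Scores are integer; gaps are affine: a gap of length g costs
// gap_open + g * gap_extend (both arguments <= 0). 'N' never counts as a
// match and always scores as a mismatch.

static const int NEG = INT_MIN / 4;  // headroom for one more subtraction

static inline bool is_match(char x, char y) {
  return x == y && x != 'N' && x != 'n';
}

// keep (score, matches) pairs; ties on score resolved toward more matches
static inline void take_max(int s, int c, int &bs, int &bc) {
  if (s > bs || (s == bs && c > bc)) { bs = s; bc = c; }
}

// End-gap-free ("overlap") alignment of a vs b. Terminal gaps in either
// sequence are unpenalised, so a short fragment fully contained in a longer
// sequence aligns without end penalties. Returns best score and the number
// of identically aligned (non-N) bases on an optimal-score path (ties
// resolved toward more matches).
static void overlap_core(const std::string &a, const std::string &b,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int &best, int &best_matches) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fprev(n + 1, NEG),
      Fcur(n + 1, NEG), cHprev(n + 1, 0), cHcur(n + 1, 0), cFprev(n + 1, 0),
      cFcur(n + 1, 0);
  best = 0;        // empty overlap is always available (free end gaps)
  best_matches = 0;
  const int ge = gap_extend, goe = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    int *hp = Hprev.data(), *hc = Hcur.data();
    int *fp = Fprev.data(), *fc = Fcur.data();
    int *chp = cHprev.data(), *chc = cHcur.data();
    int *cfp = cFprev.data(), *cfc = cFcur.data();
    hc[0] = 0; chc[0] = 0;              // free leading gap in b
    int E = NEG, cE = 0;                // gap in a, current row
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = hc[j - 1] + goe, ce = chc[j - 1];
      take_max(E + ge, cE, e, ce);
      E = e; cE = ce;
      int f = hp[j] + goe, cf = chp[j];
      take_max(fp[j] + ge, cfp[j], f, cf);
      fc[j] = f; cfc[j] = cf;
      const bool mt = is_match(ai, b[j - 1]);
      int h = hp[j - 1] + (mt ? match : mismatch);
      int ch = chp[j - 1] + (mt ? 1 : 0);
      take_max(E, cE, h, ch);
      take_max(f, cf, h, ch);
      hc[j] = h; chc[j] = ch;
    }
    take_max(hc[n], chc[n], best, best_matches);  // free trailing gap in b
    std::swap(Hprev, Hcur); std::swap(cHprev, cHcur);
    std::swap(Fprev, Fcur); std::swap(cFprev, cFcur);
  }
  for (int j = 0; j <= n; ++j)                    // free trailing gap in a
    take_max(Hprev[j], cHprev[j], best, best_matches);
}

// Smith-Waterman local alignment, score only (Gotoh affine gaps).
static int local_core(const std::string &a, const std::string &b, int match,
                      int mismatch, int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fprev(n + 1, NEG),
      Fcur(n + 1, NEG);
  int best = 0;
  const int ge = gap_extend, goe = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    int *hp = Hprev.data(), *hc = Hcur.data();
    int *fp = Fprev.data(), *fc = Fcur.data();
    hc[0] = 0;
    int E = NEG;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      E = std::max(hc[j - 1] + goe, E + ge);
      fc[j] = std::max(hp[j] + goe, fp[j] + ge);
      int h = hp[j - 1] + (is_match(ai, b[j - 1]) ? match : mismatch);
      h = std::max(h, E);
      h = std::max(h, fc[j]);
      h = std::max(h, 0);
      hc[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector overlap_align_cpp(std::string a, std::string b, int match,
                                int mismatch, int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("empty sequence in overlap alignment");
  int s, c;
  overlap_core(a, b, match, mismatch, gap_open, gap_extend, s, c);
  return NumericVector::create(_["score"] = (double)s,
                               _["matches"] = (double)c);
}

// [[Rcpp::export]]
NumericMatrix overlap_align_batch_cpp(std::string query,
                                      CharacterVector subjects, int match,
                                      int mismatch, int gap_open,
                                      int gap_extend) {
  const int k = subjects.size();
  NumericMatrix out(k, 2);
  colnames(out) = CharacterVector::create("score", "matches");
  for (int i = 0; i < k; ++i) {
    std::string b = as<std::string>(subjects[i]);
    if (query.empty() || b.empty()) stop("empty sequence in overlap alignment");
    int s, c;
    overlap_core(query, b, match, mismatch, gap_open, gap_extend, s, c);
    out(i, 0) = (double)s;
    out(i, 1) = (double)c;
  }
  return out;
}

// [[Rcpp::export]]
double local_score_cpp(std::string a, std::string b, int match, int mismatch,
                       int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("empty sequence in local alignment");
  return (double)local_core(a, b, match, mismatch, gap_open, gap_extend);
}

// [[Rcpp::export]]
NumericVector local_score_batch_cpp(std::string query,
                                    CharacterVector subjects, int match,
                                    int mismatch, int gap_open,
                                    int gap_extend) {
  const int k = subjects.size();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    std::string b = as<std::string>(subjects[i]);
    if (query.empty() || b.empty()) stop("empty sequence in local alignment");
    out[i] = (double)local_core(query, b, match, mismatch, gap_open,
                                gap_extend);
  }
  return out;
}
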