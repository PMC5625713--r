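#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Full affine-gap Smith-Waterman local alignment with a shared-word
// prefilter. Scoring follows the bl2seq regime used for dsRNA searches:
// match +2, mismatch -3, gap of length g costs open + g*extend
// (defaults open 5, extend 2). N matches nothing.

static inline bool word_shared(const std::string &a, const std::string &b, int w) {
  if (w <= 0) return true;
  if ((int)a.size() < w || (int)b.size() < w) return false;
  std::unordered_set<uint64_t> words;
  auto code_at = [w](const std::string &s, size_t p, uint64_t &out) {
    uint64_t c = 0;
    for (int i = 0; i < w; ++i) {
      char ch = s[p + i];
      int b2;
      switch (ch) {
      case 'A': b2 = 0; break; case 'C': b2 = 1; break;
      case 'G': b2 = 2; break; case 'T': b2 = 3; break;
      default: return false;
      }
      c = (c << 2) | (uint64_t)b2;
    }
    out = c;
    return true;
  };
  uint64_t c;
  for (size_t p = 0; p + w <= b.size(); ++p)
    if (code_at(b, p, c)) words.insert(c);
  for (size_t p = 0; p + w <= a.size(); ++p)
    if (code_at(a, p, c) && words.count(c)) return true;
  return false;
}

// [[Rcpp::export]]
List cpp_sw_local(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_extend, int word_size) {
  for (char &c : query) c = toupper(c);
  for (char &c : subject) c = toupper(c);
  int n = (int)query.size(), m = (int)subject.size();
  List none = List::create(
    _["score"] = 0.0, _["identity"] = NA_REAL, _["aligned_length"] = 0,
    _["n_match"] = 0, _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
    _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER, _["gaps"] = 0);
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (!word_shared(query, subject, word_size)) return none;

  const double NEG = -1e18;
  std::vector<double> M((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((size_t)(n + 1) * (m + 1), NEG); // gap in subject (consume query)
  std::vector<double> Iy((size_t)(n + 1) * (m + 1), NEG); // gap in query (consume subject)
  // traceback: 0 none/stop, 1 diag-from-M, 2 from-Ix, 3 from-Iy (for M)
  std::vector<uint8_t> tbM((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbIx((size_t)(n + 1) * (m + 1), 0); // 1 open-from-M, 2 extend
  std::vector<uint8_t> tbIy((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      size_t up = idx - (m + 1), left = idx - 1, diag = up - 1;
      // Ix: gap in subject, consume query base i
      double openx = M[up] - gap_open - gap_extend;
      double extx  = Ix[up] - gap_extend;
      if (openx >= extx) { Ix[idx] = openx; tbIx[idx] = 1; }
      else               { Ix[idx] = extx;  tbIx[idx] = 2; }
      // Iy: gap in query, consume subject base j
      double openy = M[left] - gap_open - gap_extend;
      double exty  = Iy[left] - gap_extend;
      if (openy >= exty) { Iy[idx] = openy; tbIy[idx] = 1; }
      else               { Iy[idx] = exty;  tbIy[idx] = 2; }
      // M: diagonal
      char sc = subject[j - 1];
      bool is_match = (qc == sc) && qc != 'N' && sc != 'N';
      double sub = is_match ? match : -std::abs(mismatch);
      double dM = M[diag] + sub, dX = Ix[diag] + sub, dY = Iy[diag] + sub;
      double v = dM; uint8_t t = 1;
      if (dX > v) { v = dX; t = 2; }
      if (dY > v) { v = dY; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      M[idx] = v; tbM[idx] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return none;

  // traceback from (bi, bj) in M
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  int q_end = bi, s_end = bj, q_start = bi, s_start = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t t = tbM[idx];
      if (t == 0) break;
      bool is_match = (query[i - 1] == subject[j - 1]) &&
                      query[i - 1] != 'N' && subject[j - 1] != 'N';
      if (is_match) n_match++; else n_mismatch++;
      q_start = i; s_start = j;
      i--; j--;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {  // Ix consumed query base i
      n_gap++;
      q_start = i;
      uint8_t t = tbIx[idx];
      i--;
      state = (t == 1) ? 0 : 1;
    } else {                   // Iy consumed subject base j
      n_gap++;
      s_start = j;
      uint8_t t = tbIy[idx];
      j--;
      state = (t == 1) ? 0 : 2;
    }
  }
  int aligned_len = n_match + n_mismatch + n_gap;
  // identity over aligned columns, gaps counted as mismatches
  double identity = aligned_len > 0 ? (double)n_match / aligned_len : NA_REAL;
  return List::create(
    _["score"] = best, _["identity"] = identity,
    _["aligned_length"] = aligned_len, _["n_match"] = n_match,
    _["q_start"] = q_start - 1, _["q_end"] = q_end,     // 0-based half-open
    _["s_start"] = s_start - 1, _["s_end"] = s_end,
    _["gaps"] = n_gap);
}
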