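#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman). Gap of length L costs
// gap_open + L * gap_extend (both negative). 'N' never matches anything,
// including another 'N'.

static inline bool is_match(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

static const int NEG = std::numeric_limits<int>::min() / 4;

// Score-only scan over the full subject. Returns c(score, qend, send) with
// 0-based exclusive end coordinates of the best-scoring cell. Ties prefer the
// smaller subject end, then the smaller query end.
// [[Rcpp::export]]
IntegerVector sw_scan_cpp(std::string q, std::string s,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), F(m + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int eo = Hcur[j - 1] + gap_open + gap_extend;
      const int ee = E + gap_extend;
      E = eo > ee ? eo : ee;
      const int fo = Hprev[j] + gap_open + gap_extend;
      const int fe = F[j] + gap_extend;
      F[j] = fo > fe ? fo : fe;
      const int sub = Hprev[j - 1] + (is_match(qc, s[j - 1]) ? match : mismatch);
      int h = 0;
      if (sub > h) h = sub;
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      Hcur[j] = h;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
  }
  return IntegerVector::create(best, bi, bj);
}

// Full DP with traceback; intended for a bounded window around a scan hit.
// Returns score, 0-based half-open query and subject spans of the optimal
// local alignment, the number of matched columns and the total alignment
// columns. Ties broken as in sw_scan_cpp.
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // traceback codes: H: 0 stop, 1 diag, 2 from E, 3 from F
  //                  E/F: 0 opened from H, 1 extended
  std::vector<unsigned char> tH((n + 1) * W, 0), tE((n + 1) * W, 0),
      tF((n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int eo = H[idx - 1] + gap_open + gap_extend;
      const int ee = E[idx - 1] + gap_extend;
      if (eo >= ee) { E[idx] = eo; tE[idx] = 0; } else { E[idx] = ee; tE[idx] = 1; }
      const int up = idx - W;
      const int fo = H[up] + gap_open + gap_extend;
      const int fe = F[up] + gap_extend;
      if (fo >= fe) { F[idx] = fo; tF[idx] = 0; } else { F[idx] = fe; tF[idx] = 1; }
      const int sub = H[up - 1] + (is_match(qc, s[j - 1]) ? match : mismatch);
      int h = 0; unsigned char t = 0;
      if (sub > h) { h = sub; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tH[idx] = t;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  // traceback
  int i = bi, j = bj, nmatch = 0, ncols = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      const unsigned char t = tH[idx];
      if (t == 0) break;
      if (t == 1) {
        if (is_match(q[i - 1], s[j - 1])) ++nmatch;
        ++ncols; --i; --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      const unsigned char t = tE[idx];
      ++ncols; --j;
      if (t == 0) state = 0;
    } else {
      const unsigned char t = tF[idx];
      ++ncols; --i;
      if (t == 0) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["nmatch"] = nmatch, _["ncols"] = ncols);
}
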