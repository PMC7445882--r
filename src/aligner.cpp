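#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// Infix ("semi-global") Levenshtein distance of `pattern` against any
// substring of `text`: free leading/trailing gaps in text, global in pattern.
// Returns the minimal distance, the 0-based start offset of the best
// placement and its end offset (exclusive). Ties resolved toward the
// smallest end offset, then the smallest start.
// [[Rcpp::export(name = ".infix_levenshtein")]]
List infix_levenshtein_cpp(std::string pattern, std::string text) {
  int m = (int)pattern.size(), n = (int)text.size();
  std::vector<int> prev(n + 1), cur(n + 1), sprev(n + 1), scur(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int st = sprev[j - 1];
      int del = prev[j] + 1;                  // consume pattern only
      if (del < best || (del == best && sprev[j] < st)) { best = del; st = sprev[j]; }
      int ins = cur[j - 1] + 1;               // consume text only
      if (ins < best || (ins == best && scur[j - 1] < st)) { best = ins; st = scur[j - 1]; }
      cur[j] = best; scur[j] = st;
    }
    std::swap(prev, cur); std::swap(sprev, scur);
  }
  int bestd = prev[0], bj = 0;
  for (int j = 1; j <= n; ++j) if (prev[j] < bestd) { bestd = prev[j]; bj = j; }
  return List::create(_["distance"] = bestd,
                      _["offset"] = sprev[bj],
                      _["match_end"] = bj);
}

// Banded ends-free (overlap) alignment with affine gaps.
// target = rows (i), read = cols (j). Leading and trailing gaps in either
// sequence are free: paths start on row 0 / column 0 with score 0 and end
// anywhere on the last row / last column. A gap of length k costs
// gap_open + k * gap_ext. Band: cells with  j - i  in [dlo, dhi] where
// dlo = min(0, n2-n1) - band, dhi = max(0, n2-n1) + band.
//
// Returns score, traceback ops (0 = match/mismatch, 1 = deletion in read /
// gap consuming target, 2 = insertion in read), 0-based target and read
// indices per op (insertions carry the index of the *preceding* target
// base, -1 before position 0), and whether the optimal path touched the
// band boundary (caller widens the band and retries).
// [[Rcpp::export(name = ".banded_align")]]
List banded_align_cpp(std::string target, std::string read,
                      int match, int mismatch,
                      int gap_open, int gap_ext, int band) {
  int n1 = (int)target.size(), n2 = (int)read.size();
  if (n1 == 0 || n2 == 0) stop("empty sequence");
  int dlo = std::min(0, n2 - n1) - band;
  int dhi = std::max(0, n2 - n1) + band;
  int W = dhi - dlo + 1;
  size_t total = (size_t)(n1 + 1) * (size_t)W;
  std::vector<int> M(total, NEG), X(total, NEG), Y(total, NEG);
  std::vector<unsigned char> tM(total, 0), tX(total, 0), tY(total, 0);
  int go = gap_open + gap_ext;  // cost of the first gap base

  for (int i = 1; i <= n1; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(n2, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t id = (size_t)i * W + (j - i - dlo);
      // --- M: align target[i-1] with read[j-1]
      {
        int s = (target[i - 1] == read[j - 1]) ? match : mismatch;
        int best, code;
        if (i - 1 == 0 || j - 1 == 0) { best = 0; code = 1; }
        else {
          int od = (j - 1) - (i - 1);
          if (od >= dlo && od <= dhi) {
            size_t pd = (size_t)(i - 1) * W + (od - dlo);
            best = M[pd]; code = 2;
            if (X[pd] > best) { best = X[pd]; code = 3; }
            if (Y[pd] > best) { best = Y[pd]; code = 4; }
          } else { best = NEG; code = 0; }
        }
        if (best > NEG / 2) { M[id] = best + s; tM[id] = (unsigned char)code; }
      }
      // --- X: gap consuming target (deletion in read), from (i-1, j)
      {
        int od = j - (i - 1);
        if (od >= dlo && od <= dhi) {
          size_t pu = (size_t)(i - 1) * W + (od - dlo);
          int open, ocode;
          if (i - 1 == 0) { open = 0; ocode = 1; }
          else {
            open = M[pu]; ocode = 2;
            if (Y[pu] > open) { open = Y[pu]; ocode = 3; }
          }
          int best = NEG, code = 0;
          if (open > NEG / 2) { best = open + go; code = ocode; }
          if (X[pu] > NEG / 2 && X[pu] + gap_ext > best) { best = X[pu] + gap_ext; code = 4; }
          if (best > NEG / 2) { X[id] = best; tX[id] = (unsigned char)code; }
        }
      }
      // --- Y: gap consuming read (insertion in read), from (i, j-1)
      {
        int od = (j - 1) - i;
        if (od >= dlo && od <= dhi) {
          size_t pl = (size_t)i * W + (od - dlo);
          int open, ocode;
          if (j - 1 == 0) { open = 0; ocode = 1; }
          else {
            open = M[pl]; ocode = 2;
            if (X[pl] > open) { open = X[pl]; ocode = 3; }
          }
          int best = NEG, code = 0;
          if (open > NEG / 2) { best = open + go; code = ocode; }
          if (Y[pl] > NEG / 2 && Y[pl] + gap_ext > best) { best = Y[pl] + gap_ext; code = 4; }
          if (best > NEG / 2) { Y[id] = best; tY[id] = (unsigned char)code; }
        }
      }
    }
  }

  // best end cell on last row or last column
  int bscore = NEG, bi = -1, bj = -1, bstate = 0;
  auto consider = [&](int i, int j) {
    int od = j - i;
    if (od < dlo || od > dhi) return;
    size_t id = (size_t)i * W + (od - dlo);
    if (M[id] > bscore) { bscore = M[id]; bi = i; bj = j; bstate = 0; }
    if (X[id] > bscore) { bscore = X[id]; bi = i; bj = j; bstate = 1; }
    if (Y[id] > bscore) { bscore = Y[id]; bi = i; bj = j; bstate = 2; }
  };
  for (int j = std::max(1, n1 + dlo); j <= n2; ++j) consider(n1, j);
  for (int i = std::max(1, n2 - dhi); i <= n1; ++i) consider(i, n2);
  if (bscore <= NEG / 2) stop("band too narrow: no feasible alignment path");

  // traceback
  std::vector<int> op, ti, ri;
  bool touched = false;
  int i = bi, j = bj, state = bstate;
  while (i > 0 && j > 0) {
    int od = j - i;
    if ((od == dlo || od == dhi) && i > 0 && j > 0 && i < n1 && j < n2)
      touched = true;
    size_t id = (size_t)i * W + (od - dlo);
    if (state == 0) {
      op.push_back(0); ti.push_back(i - 1); ri.push_back(j - 1);
      int c = tM[id];
      --i; --j;
      if (c == 1) break;
      state = (c == 2) ? 0 : (c == 3) ? 1 : 2;
    } else if (state == 1) {
      op.push_back(1); ti.push_back(i - 1); ri.push_back(-1);
      int c = tX[id];
      --i;
      if (c == 1) break;
      state = (c == 2) ? 0 : (c == 3) ? 2 : 1;
    } else {
      op.push_back(2); ti.push_back(i - 1); ri.push_back(j - 1);
      int c = tY[id];
      --j;
      if (c == 1) break;
      state = (c == 2) ? 0 : (c == 3) ? 1 : 2;
    }
  }
  std::reverse(op.begin(), op.end());
  std::reverse(ti.begin(), ti.end());
  std::reverse(ri.begin(), ri.end());
  return List::create(_["score"] = bscore,
                      _["op"] = IntegerVector(op.begin(), op.end()),
                      _["ti"] = IntegerVector(ti.begin(), ti.end()),
                      _["ri"] = IntegerVector(ri.begin(), ri.end()),
                      _["touched"] = touched);
}
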