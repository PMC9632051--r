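#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// Banded affine-gap (Gotoh) aligner. A gap of length L costs open + ext * L
// (the Biostrings convention). States: M (diagonal), X (gap in b, consumes a,
// cigar 'I'), Y (gap in a, consumes b, cigar 'D').
//
// mode 0: global  — path (0,0) -> (n,m).
// mode 1: extend  — path starts at (0,0), ends at the best cell on the
//                   boundary i == n or j == m (one sequence exhausted).
// mode 2: glocal  — a global, b local at both ends: start (0, j0) free,
//                   end at the best (n, j1).
//
// The band restricts column j at row i to |j - c_i| <= band with a per-mode
// center line c_i. `touched` reports whether the optimal path hit the band
// boundary (callers may retry with a doubled band).

static const int NEG = INT_MIN / 4;

static inline int subScore(char x, char y, int match, int mismatch) {
  return (x == y && x != 'N') ? match : mismatch;
}

// [[Rcpp::export]]
List align_banded_cpp(std::string a, std::string b, int band, int mode,
                      int match, int mismatch, int gapOpen, int gapExt) {
  int n = (int)a.size(), m = (int)b.size();
  int go = gapOpen + gapExt, ge = gapExt;

  // trivial sequences
  if (n == 0 || m == 0) {
    std::string cig;
    int score = 0, aend = 0, bend = 0;
    if (mode == 0) {
      if (n > 0) { cig = std::to_string(n) + "I"; score = -(gapOpen + gapExt * n); aend = n; }
      else if (m > 0) { cig = std::to_string(m) + "D"; score = -(gapOpen + gapExt * m); bend = m; }
    } else if (mode == 2 && n == 0) {
      bend = 0;
    } else if (mode == 1) {
      // boundary reached immediately at (0,0)
    }
    return List::create(_["score"] = score, _["cigar"] = cig,
                        _["touched"] = false, _["aend"] = aend,
                        _["bstart"] = 0, _["bend"] = bend,
                        _["nmatch"] = 0, _["ncols"] = (mode == 0 ? n + m : 0));
  }
  if (band < 1) stop("band must be >= 1");

  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    long c;
    if (mode == 1) c = std::min((long)i, (long)m);
    else if (mode == 2) c = (long)i + (m - n) / 2;
    else c = (long)((double)i * m / n + 0.5);
    long l = c - band, h = c + band;
    lo[i] = (int)std::max(0L, l);
    hi[i] = (int)std::min((long)m, h);
    if (lo[i] > hi[i]) { lo[i] = std::max(0, std::min(m, lo[i])); hi[i] = lo[i]; }
  }
  int W = 2 * band + 2;
  // packed traceback: 2 bits per state; value 3 = start/invalid
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0xFF);
  std::vector<int> pM(W), pX(W), pY(W), cM(W), cX(W), cY(W);

  auto tbAt = [&](int i, int j) -> uint8_t & {
    return tb[(size_t)i * W + (j - lo[i])];
  };

  // row 0
  for (int idx = 0; idx < W; ++idx) { pM[idx] = pX[idx] = pY[idx] = NEG; }
  for (int j = lo[0]; j <= hi[0]; ++j) {
    int idx = j - lo[0];
    uint8_t t = 0xFF;
    if (mode == 2) { pM[idx] = 0; t = (t & ~0x03u) | 3; }
    else if (j == 0) { pM[idx] = 0; t = (t & ~0x03u) | 3; }
    if (mode != 2 && j > lo[0]) {
      // Y along row 0 (leading deletion) — only meaningful from j-1
      int fromM = (pM[idx - 1] == NEG) ? NEG : pM[idx - 1] - go;
      int fromY = (pY[idx - 1] == NEG) ? NEG : pY[idx - 1] - ge;
      if (fromM >= fromY && fromM > NEG) { pY[idx] = fromM; t = (t & ~0x30u) | (0 << 4); }
      else if (fromY > NEG) { pY[idx] = fromY; t = (t & ~0x30u) | (2 << 4); }
    }
    tbAt(0, j) = t;
  }

  // boundary tracking for mode 1 (best cell with i == n or j == m)
  int bi = -1, bj = -1, bstate = 0, bscore = NEG;
  auto consider = [&](int i, int j, int st, int v) {
    if (v > bscore) { bscore = v; bi = i; bj = j; bstate = st; }
  };
  if (mode == 1 && hi[0] == m) {
    int idx = m - lo[0];
    consider(0, m, 0, pM[idx]);
    consider(0, m, 2, pY[idx]);
  }

  for (int i = 1; i <= n; ++i) {
    for (int idx = 0; idx < W; ++idx) { cM[idx] = cX[idx] = cY[idx] = NEG; }
    char ac = a[i - 1];
    for (int j = lo[i]; j <= hi[i]; ++j) {
      uint8_t t = 0xFF;
      int jm1p = j - 1 - lo[i - 1]; // (i-1, j-1) index in prev row
      int jp = j - lo[i - 1];       // (i-1, j)
      int jc1 = j - 1 - lo[i];      // (i, j-1)
      bool diagOK = j >= 1 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1];
      bool upOK = j >= lo[i - 1] && j <= hi[i - 1];
      bool leftOK = j - 1 >= lo[i];
      int vM = NEG, vX = NEG, vY = NEG;
      if (diagOK) {
        int s = subScore(ac, b[j - 1], match, mismatch);
        int bestPrev = NEG; int bestSt = 3;
        if (pM[jm1p] > bestPrev) { bestPrev = pM[jm1p]; bestSt = 0; }
        if (pX[jm1p] > bestPrev) { bestPrev = pX[jm1p]; bestSt = 1; }
        if (pY[jm1p] > bestPrev) { bestPrev = pY[jm1p]; bestSt = 2; }
        if (bestPrev > NEG) { vM = bestPrev + s; t = (t & ~0x03u) | bestSt; }
      }
      if (upOK) {
        int fM = (pM[jp] == NEG) ? NEG : pM[jp] - go;
        int fX = (pX[jp] == NEG) ? NEG : pX[jp] - ge;
        int fY = (pY[jp] == NEG) ? NEG : pY[jp] - go;
        int bv = NEG; int bs = 3;
        if (fM > bv) { bv = fM; bs = 0; }
        if (fX > bv) { bv = fX; bs = 1; }
        if (fY > bv) { bv = fY; bs = 2; }
        if (bv > NEG) { vX = bv; t = (t & ~0x0Cu) | (bs << 2); }
      }
      if (leftOK) {
        int fM = (cM[jc1] == NEG) ? NEG : cM[jc1] - go;
        int fX = (cX[jc1] == NEG) ? NEG : cX[jc1] - go;
        int fY = (cY[jc1] == NEG) ? NEG : cY[jc1] - ge;
        int bv = NEG; int bs = 3;
        if (fM > bv) { bv = fM; bs = 0; }
        if (fY > bv) { bv = fY; bs = 2; }
        if (fX > bv) { bv = fX; bs = 1; }
        if (bv > NEG) { vY = bv; t = (t & ~0x30u) | (bs << 4); }
      }
      int idx = j - lo[i];
      cM[idx] = vM; cX[idx] = vX; cY[idx] = vY;
      tbAt(i, j) = t;
      if (mode == 1 && (j == m || i == n)) {
        consider(i, j, 0, vM); consider(i, j, 1, vX); consider(i, j, 2, vY);
      }
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
    if (i == n) { std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY); }
    // keep last row in cM/cX/cY after loop ends
    if (i == n) break;
  }
  // after the loop, cM/cX/cY hold row n scores (see swap dance above)
  std::vector<int> &rM = cM, &rX = cX, &rY = cY;

  // pick end cell
  if (mode == 0) {
    if (m < lo[n] || m > hi[n]) stop("band does not reach the global end cell");
    int idx = m - lo[n];
    consider(n, m, 0, rM[idx]);
    consider(n, m, 1, rX[idx]);
    consider(n, m, 2, rY[idx]);
  } else if (mode == 2) {
    for (int j = lo[n]; j <= hi[n]; ++j) {
      int idx = j - lo[n];
      consider(n, j, 0, rM[idx]);
      consider(n, j, 1, rX[idx]);
      consider(n, j, 2, rY[idx]);
    }
  }
  // mode 1: bscore/bi/bj/bstate were tracked during the DP
  if (bscore <= NEG)
    stop("no alignment found within the band");

  // traceback
  std::string ops;
  ops.reserve(n + m);
  int i = bi, j = bj, st = bstate;
  bool touched = false;
  int nmatch = 0;
  while (true) {
    if ((j == lo[i] && lo[i] > 0) || (j == hi[i] && hi[i] < m)) touched = true;
    uint8_t t = tbAt(i, j);
    int pred;
    if (st == 0) pred = t & 0x03;
    else if (st == 1) pred = (t >> 2) & 0x03;
    else pred = (t >> 4) & 0x03;
    if (st == 0) {
      if (pred == 3) break; // start cell in state M
      char op = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? '=' : 'X';
      if (op == '=') ++nmatch;
      ops.push_back(op);
      --i; --j; st = pred;
    } else if (st == 1) {
      ops.push_back('I');
      --i; st = pred;
      if (pred == 3) stop("traceback error in state X");
    } else {
      ops.push_back('D');
      --j; st = pred;
      if (pred == 3) stop("traceback error in state Y");
    }
    if (i == 0 && st == 0) {
      uint8_t t0 = tbAt(0, j);
      if ((t0 & 0x03) == 3) break;
    }
  }
  int bstartCol = j;
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  size_t p = 0;
  int ncols = (int)ops.size();
  while (p < ops.size()) {
    size_t q = p + 1;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  return List::create(_["score"] = bscore, _["cigar"] = cig,
                      _["touched"] = touched, _["aend"] = bi,
                      _["bstart"] = bstartCol, _["bend"] = bj,
                      _["nmatch"] = nmatch, _["ncols"] = ncols);
}
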