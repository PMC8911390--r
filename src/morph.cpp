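#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 8-neighborhood ring, clockwise from north.
// index: 0 N, 1 NE, 2 E, 3 SE, 4 S, 5 SW, 6 W, 7 NW
static const int RDY[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RDX[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Simple-point lookup table for 8-connected foreground / 4-connected
// background. A foreground pixel is "simple" iff removing it leaves both
// the foreground and the background topology of its 3x3 neighborhood
// unchanged: exactly one 8-connected foreground component in the ring, and
// exactly one 4-connected background component in the ring that touches an
// edge-neighbor (N/E/S/W) of the center.
static bool simpleLUT[256];
static bool lutReady = false;

static int ringComponents(int code, bool value, bool eightConn,
                          bool requireEdgeTouch) {
  bool cell[8];
  for (int k = 0; k < 8; ++k) cell[k] = ((code >> k) & 1) != 0;
  bool seen[8] = {false};
  int ncomp = 0;
  for (int s = 0; s < 8; ++s) {
    if (cell[s] != value || seen[s]) continue;
    // BFS over ring cells of matching value
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    bool touches = false;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      if (a % 2 == 0) touches = true; // even ring indices are 4-neighbors
      for (int b = 0; b < 8; ++b) {
        if (cell[b] != value || seen[b]) continue;
        int ddy = RDY[a] - RDY[b], ddx = RDX[a] - RDX[b];
        int cheb = std::max(std::abs(ddy), std::abs(ddx));
        int manh = std::abs(ddy) + std::abs(ddx);
        bool adj = eightConn ? (cheb == 1) : (manh == 1);
        if (adj) { seen[b] = true; q.push(b); }
      }
    }
    if (!requireEdgeTouch || touches) ++ncomp;
  }
  return ncomp;
}

static void buildLUT() {
  if (lutReady) return;
  for (int code = 0; code < 256; ++code) {
    int fg = ringComponents(code, true, true, false);
    int bg = ringComponents(code, false, false, true);
    simpleLUT[code] = (fg == 1 && bg == 1);
  }
  lutReady = true;
}

static inline bool fgAt(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return false;
  return m(i, j) == TRUE;
}

static inline int neighborCode(const LogicalMatrix& m, int i, int j) {
  int code = 0;
  for (int k = 0; k < 8; ++k)
    if (fgAt(m, i + RDY[k], j + RDX[k])) code |= (1 << k);
  return code;
}

static inline int popcount8(int code) {
  int n = 0;
  for (int k = 0; k < 8; ++k) n += (code >> k) & 1;
  return n;
}

//' @noRd
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int nd = (connectivity == 8) ? 8 : 4;
  // 4-connectivity uses only even ring indices
  int next = 0;
  std::vector<int> qi, qj;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int k = 0; k < 8; ++k) {
          if (nd == 4 && (k % 2) == 1) continue;
          int ni = ci + RDY[k], nj = cj + RDX[k];
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (mask(ni, nj) == TRUE && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  buildLUT();
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out = clone(mask);
  // Directional subcycles (peel N, then S, then E, then W borders) keep the
  // skeleton centered. Candidates are frozen at the start of each subcycle
  // (so at most one boundary layer is peeled per direction per pass) and
  // deleted sequentially with the simple-point test re-evaluated at deletion
  // time, which guarantees exact topology preservation. Endpoints (<= 1
  // foreground neighbor) are kept.
  const int dirIdx[4] = {0, 2, 4, 6}; // N, E, S, W ring indices (rotating)
  std::vector<int> ci, cj;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      int dy = RDY[dirIdx[d]], dx = RDX[dirIdx[d]];
      ci.clear(); cj.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (out(i, j) == TRUE && !fgAt(out, i + dy, j + dx)) {
            ci.push_back(i); cj.push_back(j);
          }
        }
      }
      for (size_t k = 0; k < ci.size(); ++k) {
        int i = ci[k], j = cj[k];
        int code = neighborCode(out, i, j);
        if (popcount8(code) < 2) continue; // endpoint or isolated
        if (simpleLUT[code]) {
          out(i, j) = FALSE;
          changed = true;
        }
      }
    }
  }
  return out;
}
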