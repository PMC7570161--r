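#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman constrained so that the subject span of the
// reported local alignment covers the 0-based half-open anchor interval
// [a, b): the alignment must start at a subject column <= a and end at a
// subject column >= b - 1. A gap of length k costs open + k * ext.
// States: M (match/mismatch), X (gap in subject, consumes query),
// Y (gap in query, consumes subject). Origins are propagated for span
// reporting; ties are broken toward higher state preference (M > X > Y),
// then smaller end coordinates, giving a deterministic result.

// [[Rcpp::export]]
IntegerVector sw_anchored_cpp(IntegerVector q, IntegerVector s,
                              IntegerMatrix sub, int open, int ext,
                              int a, int b) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e15;
  // DP rows (rolling over i)
  std::vector<double> Mp(n + 1, NEG), Xp(n + 1, NEG), Yp(n + 1, NEG);
  std::vector<double> Mc(n + 1, NEG), Xc(n + 1, NEG), Yc(n + 1, NEG);
  // origins: encode (oq * (n+1) + os)
  std::vector<long> oMp(n + 1, -1), oXp(n + 1, -1), oYp(n + 1, -1);
  std::vector<long> oMc(n + 1, -1), oXc(n + 1, -1), oYc(n + 1, -1);

  double best = NEG;
  long bestOrigin = -1;
  int bestI = -1, bestJ = -1;

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    for (int j = 1; j <= n; ++j) {
      // M: align q[i-1] with s[j-1]
      double sc = sub(q[i - 1], s[j - 1]);
      double candM = NEG;
      long candO = -1;
      // fresh start at (i, j): subject start column is j-1 (0-based)
      if (j - 1 <= a) {
        candM = 0.0;
        candO = (long)(i - 1) * (n + 1) + (j - 1);
      }
      if (Mp[j - 1] > candM) { candM = Mp[j - 1]; candO = oMp[j - 1]; }
      if (Xp[j - 1] > candM) { candM = Xp[j - 1]; candO = oXp[j - 1]; }
      if (Yp[j - 1] > candM) { candM = Yp[j - 1]; candO = oYp[j - 1]; }
      if (candO >= 0) {
        Mc[j] = candM + sc;
        oMc[j] = candO;
      }
      // X: gap in subject (consume query residue i)
      double fromM = Mp[j] - open - ext;
      double fromX = Xp[j] - ext;
      if (fromM >= fromX) { Xc[j] = fromM; oXc[j] = oMp[j]; }
      else               { Xc[j] = fromX; oXc[j] = oXp[j]; }
      // Y: gap in query (consume subject residue j)
      double fromM2 = Mc[j - 1] - open - ext;
      double fromY = Yc[j - 1] - ext;
      if (fromM2 >= fromY) { Yc[j] = fromM2; oYc[j] = oMc[j - 1]; }
      else                 { Yc[j] = fromY;  oYc[j] = oYc[j - 1]; }
      // candidate alignment end (in M state) with coverage j >= b
      if (j >= b && oMc[j] >= 0) {
        if (Mc[j] > best ||
            (Mc[j] == best && (i < bestI || (i == bestI && j < bestJ)))) {
          best = Mc[j];
          bestOrigin = oMc[j];
          bestI = i;
          bestJ = j;
        }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(oMp, oMc); std::swap(oXp, oXc); std::swap(oYp, oYc);
  }

  IntegerVector out(6);
  if (bestI < 0) {
    out[0] = NA_INTEGER;
    return out;
  }
  int oq = (int)(bestOrigin / (n + 1));
  int os = (int)(bestOrigin % (n + 1));
  out[0] = (int)best;
  out[1] = oq;      // query start, 0-based
  out[2] = bestI;   // query end, exclusive
  out[3] = os;      // subject start, 0-based
  out[4] = bestJ;   // subject end, exclusive
  out[5] = 0;
  return out;
}
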