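#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e18;

// Scoring convention throughout: S is an n x A integer matrix of per-target-
// position scores for each alphabet code (0-based codes in q). All coordinates
// are 0-based, spans half-open.

// [[Rcpp::export]]
IntegerMatrix cpp_find_hits(const IntegerMatrix& S, const IntegerVector& q,
                            int w, int minWordScore) {
  const int n = S.nrow(), m = q.size();
  std::vector<int> ti, qi, sc;
  for (int i = 0; i + w <= n; ++i) {
    for (int j = 0; j + w <= m; ++j) {
      int s = 0;
      for (int t = 0; t < w; ++t) s += S(i + t, q[j + t]);
      if (s > minWordScore) {
        ti.push_back(i); qi.push_back(j); sc.push_back(s);
      }
    }
  }
  IntegerMatrix out(ti.size(), 3);
  for (size_t r = 0; r < ti.size(); ++r) {
    out(r, 0) = ti[r]; out(r, 1) = qi[r]; out(r, 2) = sc[r];
  }
  colnames(out) = CharacterVector::create("target_start", "query_start", "score");
  return out;
}

// Ungapped extension of word hits into HSPs. Hits are processed in the order
// given; every constructed HSP consumes the hits it covers (per-diagonal
// occupancy), and later extensions on the same diagonal are bounded by
// occupied intervals, so accepted HSP spans on a diagonal are disjoint.
// [[Rcpp::export]]
IntegerMatrix cpp_extend_ungapped(const IntegerMatrix& S, const IntegerVector& q,
                                  const IntegerMatrix& hits, int w,
                                  int dropoff, int minHspScore) {
  const int n = S.nrow(), m = q.size();
  std::map<int, std::vector<std::pair<int, int> > > occ; // diag -> target intervals
  std::vector<int> xs_, xe_, ys_, ye_, sc_;
  for (int r = 0; r < hits.nrow(); ++r) {
    const int i = hits(r, 0), j = hits(r, 1), d = i - j;
    std::vector<std::pair<int, int> >& iv = occ[d];
    // consumed if the hit overlaps an existing HSP on its diagonal
    bool consumed = false;
    int leftBound = std::max(0, d);           // diagonal start (target coord)
    int rightBound = std::min(n, m + d);      // diagonal end
    for (size_t k = 0; k < iv.size(); ++k) {
      if (i < iv[k].second && i + w > iv[k].first) { consumed = true; break; }
      if (iv[k].second <= i) leftBound = std::max(leftBound, iv[k].second);
      if (iv[k].first >= i + w) rightBound = std::min(rightBound, iv[k].first);
    }
    if (consumed) continue;
    int hitScore = hits(r, 2);
    // extend right
    int cur = hitScore, best = hitScore, be = i + w;
    for (int t = i + w; t < rightBound; ++t) {
      cur += S(t, q[t - d]);
      if (cur > best) { best = cur; be = t + 1; }
      else if (cur < best - dropoff) break;
    }
    // extend left from the right-trimmed segment
    cur = best;
    int bs = i;
    for (int t = i - 1; t >= leftBound; --t) {
      cur += S(t, q[t - d]);
      if (cur > best) { best = cur; bs = t; }
      else if (cur < best - dropoff) break;
    }
    iv.push_back(std::make_pair(bs, be));
    if (best > minHspScore) {
      xs_.push_back(bs); xe_.push_back(be);
      ys_.push_back(bs - d); ye_.push_back(be - d);
      sc_.push_back(best);
    }
  }
  IntegerMatrix out(xs_.size(), 5);
  for (size_t r = 0; r < xs_.size(); ++r) {
    out(r, 0) = xs_[r]; out(r, 1) = xe_[r];
    out(r, 2) = ys_[r]; out(r, 3) = ye_[r]; out(r, 4) = sc_[r];
  }
  colnames(out) = CharacterVector::create("target_start", "target_end",
                                          "query_start", "query_end", "score");
  return out;
}

// One-directional anchored affine-gap extension from (ti0, qi0), exclusive of
// the anchor column itself. dir = +1 extends toward larger indices, -1 toward
// smaller. The recurrence maximizes the raw affine-gap score; the alignment
// length at each cell (columns along the chosen path) is tracked, and the
// best final cell is selected by the length-adjusted comparison score
// raw + alpha * length. With useFloor, any prefix whose cumulative raw score
// would exhaust `bank` (bank + value <= 0) is pruned, so an extension can
// never cross a gap the anchor's score cannot pay for. Returns the best
// cell's raw value and adjusted value (0/0 = empty extension) and the column
// path from the anchor outward (col 0 target index, col 1 query index,
// -1 = gap). Tie order everywhere: diagonal > gap-in-query (consumes target)
// > gap-in-target (consumes query).
// [[Rcpp::export]]
List cpp_extend_affine(const IntegerMatrix& S, const IntegerVector& q,
                       int ti0, int qi0, int dir,
                       double gop, double gep, double alpha,
                       double bank, bool useFloor) {
  const int n = S.nrow(), m = q.size();
  const int U = (dir > 0) ? (n - 1 - ti0) : ti0;
  const int V = (dir > 0) ? (m - 1 - qi0) : qi0;
  const double ge = gep, go = gop + gep;
  NumericMatrix M(U + 1, V + 1), Gq(U + 1, V + 1), Gt(U + 1, V + 1);
  // Gq: gap in query (consumes target rows); Gt: gap in target (consumes query)
  IntegerMatrix tM(U + 1, V + 1), tGq(U + 1, V + 1), tGt(U + 1, V + 1);
  IntegerMatrix LM(U + 1, V + 1), LGq(U + 1, V + 1), LGt(U + 1, V + 1);
  M(0, 0) = 0.0; Gq(0, 0) = NEG; Gt(0, 0) = NEG;
  for (int v = 1; v <= V; ++v) {
    M(0, v) = NEG; Gq(0, v) = NEG;
    double val = -go - (v - 1) * ge;
    if (useFloor && bank + val <= 0) val = NEG;
    Gt(0, v) = val; tGt(0, v) = (v == 1) ? 0 : 1; LGt(0, v) = v;
  }
  for (int u = 1; u <= U; ++u) {
    M(u, 0) = NEG; Gt(u, 0) = NEG;
    double val = -go - (u - 1) * ge;
    if (useFloor && bank + val <= 0) val = NEG;
    Gq(u, 0) = val; tGq(u, 0) = (u == 1) ? 0 : 1; LGq(u, 0) = u;
  }
  double bestAdj = 0.0, bestVal = 0.0; int bestU = 0, bestV = 0;
  for (int u = 1; u <= U; ++u) {
    const int trow = ti0 + dir * u;
    for (int v = 1; v <= V; ++v) {
      const double sc = S(trow, q[qi0 + dir * v]);
      // match state
      double pv = M(u - 1, v - 1); int pc = 0, pl = LM(u - 1, v - 1);
      if (Gq(u - 1, v - 1) > pv) {
        pv = Gq(u - 1, v - 1); pc = 1; pl = LGq(u - 1, v - 1);
      }
      if (Gt(u - 1, v - 1) > pv) {
        pv = Gt(u - 1, v - 1); pc = 2; pl = LGt(u - 1, v - 1);
      }
      double mv = (pv <= NEG / 2) ? NEG : pv + sc;
      if (useFloor && bank + mv <= 0) mv = NEG;
      M(u, v) = mv; tM(u, v) = pc; LM(u, v) = pl + 1;
      // gap in query (consumes target)
      double o = M(u - 1, v) - go, e = Gq(u - 1, v) - ge;
      double gv; int gc, gl;
      if (o >= e) { gv = o; gc = 0; gl = LM(u - 1, v) + 1; }
      else { gv = e; gc = 1; gl = LGq(u - 1, v) + 1; }
      if (gv <= NEG / 2) gv = NEG;
      if (useFloor && bank + gv <= 0) gv = NEG;
      Gq(u, v) = gv; tGq(u, v) = gc; LGq(u, v) = gl;
      // gap in target (consumes query)
      o = M(u, v - 1) - go; e = Gt(u, v - 1) - ge;
      if (o >= e) { gv = o; gc = 0; gl = LM(u, v - 1) + 1; }
      else { gv = e; gc = 1; gl = LGt(u, v - 1) + 1; }
      if (gv <= NEG / 2) gv = NEG;
      if (useFloor && bank + gv <= 0) gv = NEG;
      Gt(u, v) = gv; tGt(u, v) = gc; LGt(u, v) = gl;
      if (mv > NEG / 2 && mv + alpha * LM(u, v) > bestAdj) {
        bestAdj = mv + alpha * LM(u, v); bestVal = mv; bestU = u; bestV = v;
      }
    }
  }
  // traceback (best cell is always in the match state; empty if (0,0))
  std::vector<int> tpath, qpath;
  int u = bestU, v = bestV, state = 0; // 0 = M, 1 = Gq, 2 = Gt
  while (u > 0 || v > 0) {
    if (state == 0) {
      tpath.push_back(ti0 + dir * u); qpath.push_back(qi0 + dir * v);
      state = tM(u, v); --u; --v;
    } else if (state == 1) {
      tpath.push_back(ti0 + dir * u); qpath.push_back(-1);
      state = (tGq(u, v) == 0) ? 0 : 1; --u;
    } else {
      tpath.push_back(-1); qpath.push_back(qi0 + dir * v);
      state = (tGt(u, v) == 0) ? 0 : 2; --v;
    }
  }
  const int L = tpath.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) { // reverse: anchor-outward order
    path(k, 0) = tpath[L - 1 - k];
    path(k, 1) = qpath[L - 1 - k];
  }
  colnames(path) = CharacterVector::create("target", "query");
  return List::create(_["value"] = bestVal, _["adjusted"] = bestAdj,
                      _["path"] = path,
                      _["target_reach"] = bestU, _["query_reach"] = bestV);
}

// Full affine-gap Smith-Waterman local alignment with traceback.
// [[Rcpp::export]]
List cpp_smith_waterman(const IntegerMatrix& S, const IntegerVector& q,
                        double gop, double gep) {
  const int n = S.nrow(), m = q.size();
  const double go = gop + gep, ge = gep;
  NumericMatrix M(n + 1, m + 1), Gq(n + 1, m + 1), Gt(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tGq(n + 1, m + 1), tGt(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; Gq(0, j) = NEG; Gt(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = 0; Gq(i, 0) = NEG; Gt(i, 0) = NEG; }
  double bestVal = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double sc = S(i - 1, q[j - 1]);
      double pv = 0.0; int pc = 3; // 3 = fresh local start
      if (M(i - 1, j - 1) > pv) { pv = M(i - 1, j - 1); pc = 0; }
      if (Gq(i - 1, j - 1) > pv) { pv = Gq(i - 1, j - 1); pc = 1; }
      if (Gt(i - 1, j - 1) > pv) { pv = Gt(i - 1, j - 1); pc = 2; }
      double mv = pv + sc;
      if (mv < 0) mv = 0;
      M(i, j) = mv; tM(i, j) = pc;
      double o = M(i - 1, j) - go, e = Gq(i - 1, j) - ge;
      if (o >= e) { Gq(i, j) = o; tGq(i, j) = 0; } else { Gq(i, j) = e; tGq(i, j) = 1; }
      o = M(i, j - 1) - go; e = Gt(i, j - 1) - ge;
      if (o >= e) { Gt(i, j) = o; tGt(i, j) = 0; } else { Gt(i, j) = e; tGt(i, j) = 1; }
      if (mv > bestVal) { bestVal = mv; bi = i; bj = j; }
    }
  }
  std::vector<int> tpath, qpath;
  if (bestVal > 0) {
    int i = bi, j = bj, state = 0;
    for (;;) {
      if (state == 0) {
        tpath.push_back(i - 1); qpath.push_back(j - 1);
        int c = tM(i, j); --i; --j;
        if (c == 3) break;
        state = c;
      } else if (state == 1) {
        tpath.push_back(i - 1); qpath.push_back(-1);
        state = (tGq(i, j) == 0) ? 0 : 1; --i;
      } else {
        tpath.push_back(-1); qpath.push_back(j - 1);
        state = (tGt(i, j) == 0) ? 0 : 2; --j;
      }
    }
  }
  const int L = tpath.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = tpath[L - 1 - k];
    path(k, 1) = qpath[L - 1 - k];
  }
  colnames(path) = CharacterVector::create("target", "query");
  return List::create(_["score"] = bestVal, _["path"] = path);
}
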