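#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap alignment over a precomputed column-score matrix.
//
// S[i,j] is the score of aligning row-unit i of sequence/profile A against
// column-unit j of B.  Gap cost model: the first gapped position of a run
// costs gap_open, each further position gap_extend (gap_open >= gap_extend).
//
// mode 0: global with free end gaps (terminal overhangs unpenalized, shown
//         as gap columns in the returned path);
// mode 1: local (best-scoring subpath; empty alignment with score 0 allowed).
//
// Traceback is deterministic: when scores tie, diagonal beats up (gap in B)
// beats left (gap in A), and among same-move predecessors M beats X beats Y.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List affine_dp(NumericMatrix S, double gap_open, double gap_extend, int mode) {
  const int n = S.nrow(), m = S.ncol();
  const bool local = (mode == 1);

  if (n == 0 || m == 0) {
    int L = local ? 0 : (n + m);
    IntegerMatrix path(L, 2);
    if (!local) {
      for (int k = 0; k < n; ++k) { path(k, 0) = k + 1; path(k, 1) = 0; }
      for (int k = 0; k < m; ++k) { path(n + k, 0) = 0; path(n + k, 1) = k + 1; }
    }
    return List::create(_["score"] = 0.0, _["path"] = path,
                        _["a_start"] = 1, _["a_end"] = 0,
                        _["b_start"] = 1, _["b_end"] = 0);
  }

  const size_t W = (size_t)(m + 1);
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * W, NEG_INF); // gap in B, consume A ("up")
  std::vector<double> Y((size_t)(n + 1) * W, NEG_INF); // gap in A, consume B ("left")
  // predecessor state: 0=M, 1=X, 2=Y, 3=fresh start
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 3), pX((size_t)(n + 1) * W, 3),
      pY((size_t)(n + 1) * W, 3);

  M[0] = 0.0;
  if (!local) {
    // free leading overhang: alignment may start at any boundary cell
    for (int i = 1; i <= n; ++i) M[(size_t)i * W] = 0.0;
    for (int j = 1; j <= m; ++j) M[(size_t)j] = 0.0;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j, d = (size_t)(i - 1) * W + (j - 1),
                   u = (size_t)(i - 1) * W + j, l = c - 1;
      // M: diagonal move ending at (i,j); tie order M > X > Y > start
      double best = M[d];
      unsigned char p = 0;
      if (X[d] > best) { best = X[d]; p = 1; }
      if (Y[d] > best) { best = Y[d]; p = 2; }
      if (local && 0.0 >= best) { best = 0.0; p = 3; }
      M[c] = (best == NEG_INF) ? NEG_INF : best + S(i - 1, j - 1);
      pM[c] = p;
      // X: gap in B (consume A)
      double bx = (M[u] == NEG_INF) ? NEG_INF : M[u] - gap_open;
      unsigned char px = 0;
      double t = (X[u] == NEG_INF) ? NEG_INF : X[u] - gap_extend;
      if (t > bx) { bx = t; px = 1; }
      t = (Y[u] == NEG_INF) ? NEG_INF : Y[u] - gap_open;
      if (t > bx) { bx = t; px = 2; }
      X[c] = bx; pX[c] = px;
      // Y: gap in A (consume B)
      double by = (M[l] == NEG_INF) ? NEG_INF : M[l] - gap_open;
      unsigned char py = 0;
      t = (X[l] == NEG_INF) ? NEG_INF : X[l] - gap_open;
      if (t > by) { by = t; py = 1; }
      t = (Y[l] == NEG_INF) ? NEG_INF : Y[l] - gap_extend;
      if (t > by) { by = t; py = 2; }
      Y[c] = by; pY[c] = py;
    }
  }

  // locate alignment end; in free-end mode the empty core (both sequences
  // as unaligned overhangs) scores 0 and is the floor
  double best = 0.0;
  int ei = local ? 0 : n, ej = local ? 0 : m, estate = 3;
  if (local) {
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        const double v = M[(size_t)i * W + j];
        if (v > best) { best = v; ei = i; ej = j; estate = 0; }
      }
  } else {
    // free trailing overhang: end on the last row or last column, any state
    for (int j = m; j >= 1; --j) {
      const size_t c = (size_t)n * W + j;
      const double cand[3] = { M[c], X[c], Y[c] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > best) { best = cand[s]; ei = n; ej = j; estate = s; }
    }
    for (int i = n; i >= 1; --i) {
      const size_t c = (size_t)i * W + m;
      const double cand[3] = { M[c], X[c], Y[c] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > best) { best = cand[s]; ei = i; ej = m; estate = s; }
    }
  }

  // traceback; stops at a fresh-start marker or a boundary M cell
  std::vector<int> ra, rb;
  int i = ei, j = ej, st = estate;
  while (st != 3 && (i > 0 && j > 0)) {
    const size_t c = (size_t)i * W + j;
    if (st == 0) {
      unsigned char p = pM[c];
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      if (p == 3) break;
      st = p;
      if (st == 0 && (i == 0 || j == 0)) break; // boundary M = free start
    } else if (st == 1) {
      unsigned char p = pX[c];
      ra.push_back(i); rb.push_back(0);
      --i;
      st = p;
      if (st == 0 && (i == 0 || j == 0)) break;
    } else {
      unsigned char p = pY[c];
      ra.push_back(0); rb.push_back(j);
      --j;
      st = p;
      if (st == 0 && (i == 0 || j == 0)) break;
    }
  }
  const int si = i, sj = j; // alignment proper starts after (si, sj)

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  if (!local) {
    // materialize free terminal overhangs as gap columns
    std::vector<int> fa, fb;
    fa.reserve(ra.size() + si + sj + (n - ei) + (m - ej));
    for (int k = 1; k <= si; ++k) { fa.push_back(k); fb.push_back(0); }
    for (int k = 1; k <= sj; ++k) { fa.push_back(0); fb.push_back(k); }
    fa.insert(fa.end(), ra.begin(), ra.end());
    fb.insert(fb.end(), rb.begin(), rb.end());
    for (int k = ei + 1; k <= n; ++k) { fa.push_back(k); fb.push_back(0); }
    for (int k = ej + 1; k <= m; ++k) { fa.push_back(0); fb.push_back(k); }
    ra.swap(fa); rb.swap(fb);
  }

  IntegerMatrix path(ra.size(), 2);
  for (size_t k = 0; k < ra.size(); ++k) { path(k, 0) = ra[k]; path(k, 1) = rb[k]; }
  return List::create(_["score"] = best, _["path"] = path,
                      _["a_start"] = si + 1, _["a_end"] = ei,
                      _["b_start"] = sj + 1, _["b_end"] = ej);
}
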