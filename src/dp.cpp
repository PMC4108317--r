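#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b + 2^c), safe for -Inf arguments
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// transition matrix column layout (log2 probabilities, rows = nodes 0..M)
enum { MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6 };

// Profile-HMM forward log2-odds score.
// lme: M x 20 match emission log-odds (row j-1 = match state j)
// lie: (M+1) x 20 insert emission log-odds (row j = insert state j)
// ltr: (M+1) x 7 log2 transitions; row M holds exits to END in MM/IM/DM slots
// seq: residue indices 0..19, or -1 for ambiguous (scores 0 log-odds)
// local: if true, unannotated flanking residues are absorbed by background
// flank states with self-loop probability loop_p
// [[Rcpp::export]]
double phmm_forward_cpp(NumericMatrix lme, NumericMatrix lie, NumericMatrix ltr,
                        IntegerVector seq, bool local = false,
                        double loop_p = 0.9) {
  const int M = lme.nrow();
  const int n = seq.size();
  const double llo = local ? std::log2(loop_p) : NEG_INF;
  const double lex = local ? std::log2(1.0 - loop_p) : 0.0;

  std::vector<double> vmPrev(M + 1), viPrev(M + 1), vdPrev(M + 1);
  std::vector<double> vm(M + 1), vi(M + 1), vd(M + 1);
  std::vector<double> endv(n + 1, NEG_INF);

  // i = 0 column
  for (int j = 0; j <= M; ++j) { vm[j] = NEG_INF; vi[j] = NEG_INF; vd[j] = NEG_INF; }
  vm[0] = local ? lex : 0.0;  // BEGIN with zero residues emitted
  for (int j = 1; j <= M; ++j)
    vd[j] = lse2(vm[j - 1] + ltr(j - 1, MD), vd[j - 1] + ltr(j - 1, DD));
  endv[0] = lse3(vm[M] + ltr(M, MM), vi[M] + ltr(M, IM), vd[M] + ltr(M, DM));

  for (int i = 1; i <= n; ++i) {
    vmPrev = vm; viPrev = vi; vdPrev = vd;
    const int x = seq[i - 1];
    // BEGIN after i flank residues (local mode only)
    vm[0] = local ? (i * llo + lex) : NEG_INF;
    vi[0] = (x < 0 ? 0.0 : lie(0, x)) +
            lse2(vmPrev[0] + ltr(0, MI), viPrev[0] + ltr(0, II));
    for (int j = 1; j <= M; ++j) {
      double em = (x < 0) ? 0.0 : lme(j - 1, x);
      vm[j] = em + lse3(vmPrev[j - 1] + ltr(j - 1, MM),
                        viPrev[j - 1] + ltr(j - 1, IM),
                        vdPrev[j - 1] + ltr(j - 1, DM));
      double ie = (x < 0) ? 0.0 : lie(j, x);
      vi[j] = ie + lse2(vmPrev[j] + ltr(j, MI), viPrev[j] + ltr(j, II));
    }
    vd[0] = NEG_INF;
    for (int j = 1; j <= M; ++j)
      vd[j] = lse2(vm[j - 1] + ltr(j - 1, MD), vd[j - 1] + ltr(j - 1, DD));
    endv[i] = lse3(vm[M] + ltr(M, MM), vi[M] + ltr(M, IM), vd[M] + ltr(M, DM));
  }

  if (!local) return endv[n];
  // C-terminal flank: emit the remaining n - i residues from background
  double total = NEG_INF;
  for (int i = 0; i <= n; ++i)
    total = lse2(total, endv[i] + (n - i) * llo + lex);
  return total;
}

// Viterbi: max-probability path and its log2-odds score.
// Tie-break: among equal-scoring predecessors the match state is preferred
// over insert, insert over delete (strict > required to replace).
// Returns list(score, path) with path an integer matrix: col1 state type
// (0 = M, 1 = I, 2 = D), col2 node index. BEGIN/END are added by the caller.
// [[Rcpp::export]]
List phmm_viterbi_cpp(NumericMatrix lme, NumericMatrix lie, NumericMatrix ltr,
                      IntegerVector seq, bool local = false,
                      double loop_p = 0.9) {
  const int M = lme.nrow();
  const int n = seq.size();
  const double llo = local ? std::log2(loop_p) : NEG_INF;
  const double lex = local ? std::log2(1.0 - loop_p) : 0.0;

  // state codes: 0 = M (node j incl. BEGIN as M0), 1 = I, 2 = D
  // backpointer encodes predecessor state type
  auto idx = [&](int j, int i) { return j * (n + 1) + i; };
  std::vector<double> vm((M + 1) * (n + 1), NEG_INF);
  std::vector<double> vi((M + 1) * (n + 1), NEG_INF);
  std::vector<double> vd((M + 1) * (n + 1), NEG_INF);
  std::vector<signed char> bm((M + 1) * (n + 1), -1);
  std::vector<signed char> bi((M + 1) * (n + 1), -1);
  std::vector<signed char> bd((M + 1) * (n + 1), -1);

  for (int i = 0; i <= n; ++i) {
    if (i == 0) vm[idx(0, 0)] = local ? lex : 0.0;
    else if (local) { vm[idx(0, i)] = i * llo + lex; bm[idx(0, i)] = -1; }
    const int x = (i >= 1) ? seq[i - 1] : -1;
    if (i >= 1) {
      double a = vm[idx(0, i - 1)] + ltr(0, MI);
      double b = vi[idx(0, i - 1)] + ltr(0, II);
      double e0 = (x < 0) ? 0.0 : lie(0, x);
      if (b > a) { vi[idx(0, i)] = e0 + b; bi[idx(0, i)] = 1; }
      else       { vi[idx(0, i)] = e0 + a; bi[idx(0, i)] = 0; }
    }
    for (int j = 1; j <= M; ++j) {
      if (i >= 1) {
        double cm = vm[idx(j - 1, i - 1)] + ltr(j - 1, MM);
        double ci = vi[idx(j - 1, i - 1)] + ltr(j - 1, IM);
        double cd = vd[idx(j - 1, i - 1)] + ltr(j - 1, DM);
        double best = cm; signed char who = 0;
        if (ci > best) { best = ci; who = 1; }
        if (cd > best) { best = cd; who = 2; }
        double em = (x < 0) ? 0.0 : lme(j - 1, x);
        vm[idx(j, i)] = em + best; bm[idx(j, i)] = who;
        double am = vm[idx(j, i - 1)] + ltr(j, MI);
        double ai = vi[idx(j, i - 1)] + ltr(j, II);
        double ie = (x < 0) ? 0.0 : lie(j, x);
        if (ai > am) { vi[idx(j, i)] = ie + ai; bi[idx(j, i)] = 1; }
        else         { vi[idx(j, i)] = ie + am; bi[idx(j, i)] = 0; }
      }
      double dm = vm[idx(j - 1, i)] + ltr(j - 1, MD);
      double dd = vd[idx(j - 1, i)] + ltr(j - 1, DD);
      if (dd > dm) { vd[idx(j, i)] = dd; bd[idx(j, i)] = 2; }
      else         { vd[idx(j, i)] = dm; bd[idx(j, i)] = 0; }
    }
  }

  // END: choose exit column (local: any i with flank emission) and exit state
  double best = NEG_INF; int bestI = n; signed char bestS = 0;
  for (int i = local ? 0 : n; i <= n; ++i) {
    double tail = local ? ((n - i) * llo + lex) : 0.0;
    double cm = vm[idx(M, i)] + ltr(M, MM) + tail;
    double ci = vi[idx(M, i)] + ltr(M, IM) + tail;
    double cd = vd[idx(M, i)] + ltr(M, DM) + tail;
    if (cm > best) { best = cm; bestI = i; bestS = 0; }
    if (ci > best) { best = ci; bestI = i; bestS = 1; }
    if (cd > best) { best = cd; bestI = i; bestS = 2; }
  }

  // trace back
  std::vector<int> stype, snode;
  int j = M, i = bestI; signed char s = bestS;
  while (!(s == 0 && j == 0)) {
    stype.push_back(s); snode.push_back(j);
    signed char prev;
    if (s == 0)      { prev = bm[idx(j, i)]; --j; --i; }
    else if (s == 1) { prev = bi[idx(j, i)]; --i; }
    else             { prev = bd[idx(j, i)]; --j; }
    if (prev < 0) break;  // reached BEGIN (or a local-mode flank entry)
    s = prev;
  }
  const int L = stype.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = stype[L - 1 - k];
    path(k, 1) = snode[L - 1 - k];
  }
  return List::create(_["score"] = best, _["path"] = path,
                      _["exit_i"] = bestI);
}

// Forward scores for a list of integer-coded sequences.
// [[Rcpp::export]]
NumericVector phmm_score_batch_cpp(NumericMatrix lme, NumericMatrix lie,
                                   NumericMatrix ltr, List seqs,
                                   bool local = false, double loop_p = 0.9) {
  const int N = seqs.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k) {
    IntegerVector s = seqs[k];
    out[k] = phmm_forward_cpp(lme, lie, ltr, s, local, loop_p);
  }
  return out;
}

// Affine-gap global alignment of two column-frequency profiles.
// fa: 20 x La, fb: 20 x Lb (columns are residue frequencies, gaps excluded
// from the normalisation); S: 20 x 20 substitution matrix.
// Column score = fa_col' S fb_col; a gap run of length L costs go + L*ge
// (go, ge <= 0). Traceback tie-break: diagonal, then gap-in-B (consume A),
// then gap-in-A.
// Returns list(score, ops) with ops: 0 = aligned column, 1 = A-only column,
// 2 = B-only column.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                       double go, double ge) {
  const int La = fa.ncol(), Lb = fb.ncol(), A = fa.nrow();
  // precompute column scores
  NumericMatrix cs(La, Lb);
  // Sfb = S %*% fb
  std::vector<double> Sfb(A * Lb, 0.0);
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < A; ++a) {
      double acc = 0.0;
      for (int b = 0; b < A; ++b) acc += S(a, b) * fb(b, j);
      Sfb[j * A + a] = acc;
    }
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      double acc = 0.0;
      for (int a = 0; a < A; ++a) acc += fa(a, i) * Sfb[j * A + a];
      cs(i, j) = acc;
    }

  auto id = [&](int i, int j) { return i * (Lb + 1) + j; };
  std::vector<double> Mm((La + 1) * (Lb + 1), NEG_INF);
  std::vector<double> Xx((La + 1) * (Lb + 1), NEG_INF);
  std::vector<double> Yy((La + 1) * (Lb + 1), NEG_INF);
  std::vector<signed char> pM((La + 1) * (Lb + 1), -1);
  std::vector<signed char> pX((La + 1) * (Lb + 1), -1);
  std::vector<signed char> pY((La + 1) * (Lb + 1), -1);

  Mm[id(0, 0)] = 0.0;
  for (int i = 1; i <= La; ++i) { Xx[id(i, 0)] = go + i * ge; pX[id(i, 0)] = 1; }
  for (int j = 1; j <= Lb; ++j) { Yy[id(0, j)] = go + j * ge; pY[id(0, j)] = 2; }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      // diagonal
      double dm = Mm[id(i - 1, j - 1)], dx = Xx[id(i - 1, j - 1)],
             dy = Yy[id(i - 1, j - 1)];
      double best = dm; signed char who = 0;
      if (dx > best) { best = dx; who = 1; }
      if (dy > best) { best = dy; who = 2; }
      Mm[id(i, j)] = best + cs(i - 1, j - 1); pM[id(i, j)] = who;
      // gap in B (consume column of A)
      double xm = Mm[id(i - 1, j)] + go + ge, xx = Xx[id(i - 1, j)] + ge,
             xy = Yy[id(i - 1, j)] + go + ge;
      best = xm; who = 0;
      if (xx > best) { best = xx; who = 1; }
      if (xy > best) { best = xy; who = 2; }
      Xx[id(i, j)] = best; pX[id(i, j)] = who;
      // gap in A (consume column of B)
      double ym = Mm[id(i, j - 1)] + go + ge, yx = Xx[id(i, j - 1)] + go + ge,
             yy = Yy[id(i, j - 1)] + ge;
      best = ym; who = 0;
      if (yx > best) { best = yx; who = 1; }
      if (yy > best) { best = yy; who = 2; }
      Yy[id(i, j)] = best; pY[id(i, j)] = who;
    }
  }

  double fm = Mm[id(La, Lb)], fx = Xx[id(La, Lb)], fy = Yy[id(La, Lb)];
  double score = fm; signed char state = 0;
  if (fx > score) { score = fx; state = 1; }
  if (fy > score) { score = fy; state = 2; }

  std::vector<int> ops;
  int i = La, j = Lb; signed char s = state;
  while (i > 0 || j > 0) {
    if (s == 0)      { ops.push_back(0); s = pM[id(i, j)]; --i; --j; }
    else if (s == 1) { ops.push_back(1); s = pX[id(i, j)]; --i; }
    else             { ops.push_back(2); s = pY[id(i, j)]; --j; }
  }
  IntegerVector out(ops.size());
  for (size_t k = 0; k < ops.size(); ++k) out[k] = ops[ops.size() - 1 - k];
  return List::create(_["score"] = score, _["ops"] = out);
}
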