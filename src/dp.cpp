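// Three-state alignment lattice kernels shared by the Viterbi aligner, the
// ADMM subproblem solvers and the CNF training machinery.
//
// Lattice convention: a path runs from the dummy vertex (0,0) to (nT,nS).
//   M  at (i,j): columns i of T and j of S matched      (1<=i<=nT, 1<=j<=nS)
//   IT at (i,j): column i of T inserted, S progress j   (1<=i<=nT, 0<=j<=nS)
//   IS at (i,j): column j of S inserted, T progress i   (0<=i<=nT, 1<=j<=nS)
// Direct IT<->IS toggling is disallowed (affine convention).  Transitions out
// of the dummy vertex carry no bias.
//
// Score matrices (passed from R, 1-based semantics):
//   sM : nT x nS       sM(i-1, j-1)  = score of M  at (i,j)
//   sIT: nT x (nS+1)   sIT(i-1, j)   = score of IT at (i,j), j = 0..nS
//   sIS: (nT+1) x nS   sIS(i, j-1)   = score of IS at (i,j), i = 0..nT
//   trans: 3x3, rows = from-state (M,IT,IS), cols = to-state.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct Lattice {
  int nT, nS;
  std::vector<double> M, IT, IS; // (nT+1) x (nS+1), row-major
  Lattice(int nT_, int nS_) : nT(nT_), nS(nS_),
    M((nT_ + 1) * (nS_ + 1), NEG_INF),
    IT((nT_ + 1) * (nS_ + 1), NEG_INF),
    IS((nT_ + 1) * (nS_ + 1), NEG_INF) {}
  inline int idx(int i, int j) const { return i * (nS + 1) + j; }
};

// [[Rcpp::export(name = ".viterbi_dp")]]
List viterbi_dp(NumericMatrix sM, NumericMatrix sIT, NumericMatrix sIS,
                NumericMatrix trans) {
  const int nT = sM.nrow(), nS = sM.ncol();
  Lattice V(nT, nS);
  // backpointers: 0 = dummy, 1 = M, 2 = IT, 3 = IS
  std::vector<signed char> bpM(V.M.size(), -1), bpIT(V.M.size(), -1),
      bpIS(V.M.size(), -1);

  for (int i = 0; i <= nT; ++i) {
    for (int j = 0; j <= nS; ++j) {
      const int c = V.idx(i, j);
      if (i >= 1 && j >= 1) { // M from (i-1, j-1)
        const int p = V.idx(i - 1, j - 1);
        double best = NEG_INF; signed char arg = -1;
        if (i == 1 && j == 1) { best = 0.0; arg = 0; }
        double v;
        v = V.M[p] + trans(0, 0); if (v > best) { best = v; arg = 1; }
        v = V.IT[p] + trans(1, 0); if (v > best) { best = v; arg = 2; }
        v = V.IS[p] + trans(2, 0); if (v > best) { best = v; arg = 3; }
        if (arg >= 0) { V.M[c] = sM(i - 1, j - 1) + best; bpM[c] = arg; }
      }
      if (i >= 1) { // IT from (i-1, j)
        const int p = V.idx(i - 1, j);
        double best = NEG_INF; signed char arg = -1;
        if (i == 1 && j == 0) { best = 0.0; arg = 0; }
        double v;
        v = V.M[p] + trans(0, 1); if (v > best) { best = v; arg = 1; }
        v = V.IT[p] + trans(1, 1); if (v > best) { best = v; arg = 2; }
        if (arg >= 0) { V.IT[c] = sIT(i - 1, j) + best; bpIT[c] = arg; }
      }
      if (j >= 1) { // IS from (i, j-1)
        const int p = V.idx(i, j - 1);
        double best = NEG_INF; signed char arg = -1;
        if (i == 0 && j == 1) { best = 0.0; arg = 0; }
        double v;
        v = V.M[p] + trans(0, 2); if (v > best) { best = v; arg = 1; }
        v = V.IS[p] + trans(2, 2); if (v > best) { best = v; arg = 3; }
        if (arg >= 0) { V.IS[c] = sIS(i, j - 1) + best; bpIS[c] = arg; }
      }
    }
  }

  // empty-by-empty: the dummy path
  if (nT == 0 && nS == 0) {
    return List::create(_["score"] = 0.0,
                        _["path"] = IntegerMatrix(0, 3));
  }

  const int e = V.idx(nT, nS);
  double best = V.M[e]; int state = 1; // prefer M, then IT, then IS
  if (V.IT[e] > best) { best = V.IT[e]; state = 2; }
  if (V.IS[e] > best) { best = V.IS[e]; state = 3; }

  // traceback
  std::vector<int> pi, pj, pu;
  int i = nT, j = nS, u = state;
  while (u != 0) {
    pi.push_back(i); pj.push_back(j); pu.push_back(u);
    const int c = V.idx(i, j);
    int prev;
    if (u == 1)      { prev = bpM[c];  --i; --j; }
    else if (u == 2) { prev = bpIT[c]; --i; }
    else             { prev = bpIS[c]; --j; }
    u = prev;
  }
  const int n = (int) pi.size();
  IntegerMatrix path(n, 3);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = pi[n - 1 - k];
    path(k, 1) = pj[n - 1 - k];
    path(k, 2) = pu[n - 1 - k];
  }
  colnames(path) = CharacterVector::create("i", "j", "state");
  return List::create(_["score"] = best, _["path"] = path);
}

static void forward_fill(const NumericMatrix &sM, const NumericMatrix &sIT,
                         const NumericMatrix &sIS, const NumericMatrix &trans,
                         Lattice &F) {
  const int nT = F.nT, nS = F.nS;
  for (int i = 0; i <= nT; ++i) {
    for (int j = 0; j <= nS; ++j) {
      const int c = F.idx(i, j);
      if (i >= 1 && j >= 1) {
        const int p = F.idx(i - 1, j - 1);
        double acc = (i == 1 && j == 1) ? 0.0 : NEG_INF;
        acc = lse2(acc, F.M[p] + trans(0, 0));
        acc = lse2(acc, F.IT[p] + trans(1, 0));
        acc = lse2(acc, F.IS[p] + trans(2, 0));
        F.M[c] = sM(i - 1, j - 1) + acc;
      }
      if (i >= 1) {
        const int p = F.idx(i - 1, j);
        double acc = (i == 1 && j == 0) ? 0.0 : NEG_INF;
        acc = lse2(acc, F.M[p] + trans(0, 1));
        acc = lse2(acc, F.IT[p] + trans(1, 1));
        F.IT[c] = sIT(i - 1, j) + acc;
      }
      if (j >= 1) {
        const int p = F.idx(i, j - 1);
        double acc = (i == 0 && j == 1) ? 0.0 : NEG_INF;
        acc = lse2(acc, F.M[p] + trans(0, 2));
        acc = lse2(acc, F.IS[p] + trans(2, 2));
        F.IS[c] = sIS(i, j - 1) + acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".forward_logz")]]
double forward_logz(NumericMatrix sM, NumericMatrix sIT, NumericMatrix sIS,
                    NumericMatrix trans) {
  const int nT = sM.nrow(), nS = sM.ncol();
  if (nT == 0 && nS == 0) return 0.0;
  Lattice F(nT, nS);
  forward_fill(sM, sIT, sIS, trans, F);
  const int e = F.idx(nT, nS);
  return lse2(F.M[e], lse2(F.IT[e], F.IS[e]));
}

// Forward-backward: per-cell state posteriors and expected transition counts.
// [[Rcpp::export(name = ".forward_backward")]]
List forward_backward(NumericMatrix sM, NumericMatrix sIT, NumericMatrix sIS,
                      NumericMatrix trans) {
  const int nT = sM.nrow(), nS = sM.ncol();
  Lattice F(nT, nS), B(nT, nS);
  forward_fill(sM, sIT, sIS, trans, F);
  const int e = F.idx(nT, nS);
  const double logZ = lse2(F.M[e], lse2(F.IT[e], F.IS[e]));

  // backward: B_u(i,j) = log-sum over path suffixes leaving (i,j,u),
  // excluding the score of (i,j,u) itself.
  B.M[e] = 0.0; B.IT[e] = 0.0; B.IS[e] = 0.0;
  for (int i = nT; i >= 0; --i) {
    for (int j = nS; j >= 0; --j) {
      const int c = B.idx(i, j);
      if (i == nT && j == nS) continue;
      double bM = NEG_INF, bIT = NEG_INF, bIS = NEG_INF;
      if (i + 1 <= nT && j + 1 <= nS) { // successor M at (i+1, j+1)
        const double down = sM(i, j) + B.M[B.idx(i + 1, j + 1)];
        bM  = lse2(bM,  trans(0, 0) + down);
        bIT = lse2(bIT, trans(1, 0) + down);
        bIS = lse2(bIS, trans(2, 0) + down);
      }
      if (i + 1 <= nT) { // successor IT at (i+1, j)
        const double down = sIT(i, j) + B.IT[B.idx(i + 1, j)];
        bM  = lse2(bM,  trans(0, 1) + down);
        bIT = lse2(bIT, trans(1, 1) + down);
      }
      if (j + 1 <= nS) { // successor IS at (i, j+1)
        const double down = sIS(i, j) + B.IS[B.idx(i, j + 1)];
        bM  = lse2(bM,  trans(0, 2) + down);
        bIS = lse2(bIS, trans(2, 2) + down);
      }
      B.M[c] = bM; B.IT[c] = bIT; B.IS[c] = bIS;
    }
  }

  NumericMatrix PM(nT, nS), PIT(nT, nS + 1), PIS(nT + 1, nS);
  for (int i = 1; i <= nT; ++i)
    for (int j = 1; j <= nS; ++j)
      PM(i - 1, j - 1) = std::exp(F.M[F.idx(i, j)] + B.M[B.idx(i, j)] - logZ);
  for (int i = 1; i <= nT; ++i)
    for (int j = 0; j <= nS; ++j)
      PIT(i - 1, j) = std::exp(F.IT[F.idx(i, j)] + B.IT[B.idx(i, j)] - logZ);
  for (int i = 0; i <= nT; ++i)
    for (int j = 1; j <= nS; ++j)
      PIS(i, j - 1) = std::exp(F.IS[F.idx(i, j)] + B.IS[B.idx(i, j)] - logZ);

  // expected transition counts E[u -> v]
  NumericMatrix Et(3, 3);
  for (int i = 0; i <= nT; ++i) {
    for (int j = 0; j <= nS; ++j) {
      const int c = F.idx(i, j);
      const double fM = F.M[c], fIT = F.IT[c], fIS = F.IS[c];
      if (i + 1 <= nT && j + 1 <= nS) {
        const double down = sM(i, j) + B.M[B.idx(i + 1, j + 1)] - logZ;
        if (fM  != NEG_INF) Et(0, 0) += std::exp(fM  + trans(0, 0) + down);
        if (fIT != NEG_INF) Et(1, 0) += std::exp(fIT + trans(1, 0) + down);
        if (fIS != NEG_INF) Et(2, 0) += std::exp(fIS + trans(2, 0) + down);
      }
      if (i + 1 <= nT) {
        const double down = sIT(i, j) + B.IT[B.idx(i + 1, j)] - logZ;
        if (fM  != NEG_INF) Et(0, 1) += std::exp(fM  + trans(0, 1) + down);
        if (fIT != NEG_INF) Et(1, 1) += std::exp(fIT + trans(1, 1) + down);
      }
      if (j + 1 <= nS) {
        const double down = sIS(i, j) + B.IS[B.idx(i, j + 1)] - logZ;
        if (fM  != NEG_INF) Et(0, 2) += std::exp(fM  + trans(0, 2) + down);
        if (fIS != NEG_INF) Et(2, 2) += std::exp(fIS + trans(2, 2) + down);
      }
    }
  }

  return List::create(_["logZ"] = logZ, _["post_M"] = PM, _["post_IT"] = PIT,
                      _["post_IS"] = PIS, _["expected_trans"] = Et);
}
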