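#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local (Smith-Waterman-style entry/exit) profile-HMM dynamic programming
// in bit units. Inputs are precomputed log-odds:
//   msc(i,k): match-emission log-odds (bits) for residue i at match state k
//   isc(i,k): insert-emission log-odds for residue i at insert state k
//   tb(s,c):  transition log2-probabilities out of state s (rows 0..L),
//             columns MM MI MD IM II DM DD (0..6)
// The alignment may enter any match state at zero cost, exit from any
// match state at zero cost, and the empty alignment scores 0. Flanking
// residues emit from the background and cancel in log-odds.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export]]
List cpp_profile_viterbi(NumericMatrix msc, NumericMatrix isc,
                         NumericMatrix tb) {
  const int n = msc.nrow(), L = msc.ncol();
  const double NEG = R_NegInf;
  NumericMatrix M(n + 1, L + 1), I(n + 1, L + 1), D(n + 1, L + 1);
  // ptr codes: 0 entry, 1 from M, 2 from I, 3 from D
  IntegerMatrix Mp(n + 1, L + 1), Ip(n + 1, L + 1), Dp(n + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG);
  std::fill(I.begin(), I.end(), NEG);
  std::fill(D.begin(), D.end(), NEG);
  double best = 0.0;  // empty alignment
  int bi = 0, bk = 0;
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= L; ++k) {
      // M(i,k): emit residue i at match k
      double cand = 0.0; int ptr = 0;  // fresh entry
      if (k >= 2) {
        double vM = M(i - 1, k - 1) + tb(k - 1, 0);
        double vI = I(i - 1, k - 1) + tb(k - 1, 3);
        double vD = D(i - 1, k - 1) + tb(k - 1, 5);
        if (vM > cand) { cand = vM; ptr = 1; }
        if (vI > cand) { cand = vI; ptr = 2; }
        if (vD > cand) { cand = vD; ptr = 3; }
      }
      M(i, k) = msc(i - 1, k - 1) + cand;
      Mp(i, k) = ptr;
      if (M(i, k) > best) { best = M(i, k); bi = i; bk = k; }
      // I(i,k): emit residue i at insert k (k = 1..L-1 in plan7; allow
      // up to L-1 only)
      if (k < L) {
        double vM = M(i - 1, k) + tb(k, 1);
        double vI = I(i - 1, k) + tb(k, 4);
        if (vM >= vI) { I(i, k) = isc(i - 1, k - 1) + vM; Ip(i, k) = 1; }
        else          { I(i, k) = isc(i - 1, k - 1) + vI; Ip(i, k) = 2; }
      }
      // D(i,k): silent
      if (k >= 2) {
        double vM = M(i, k - 1) + tb(k - 1, 2);
        double vD = D(i, k - 1) + tb(k - 1, 6);
        if (vM >= vD) { D(i, k) = vM; Dp(i, k) = 1; }
        else          { D(i, k) = vD; Dp(i, k) = 3; }
      }
    }
  }
  int q_start = 0, q_end = 0, p_start = 0, p_end = 0;
  if (best > 0.0) {
    q_end = bi; p_end = bk;
    int i = bi, k = bk, state = 1;  // 1=M,2=I,3=D
    for (;;) {
      if (state == 1) {
        int ptr = Mp(i, k);
        if (ptr == 0) { q_start = i - 1; p_start = k - 1; break; }
        state = ptr; --i; --k;
      } else if (state == 2) {
        state = Ip(i, k); --i;
      } else {
        state = Dp(i, k); --k;
      }
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["p_start"] = p_start, _["p_end"] = p_end);
}

// [[Rcpp::export]]
double cpp_profile_forward(NumericMatrix msc, NumericMatrix isc,
                           NumericMatrix tb) {
  const int n = msc.nrow(), L = msc.ncol();
  const double NEG = R_NegInf;
  NumericMatrix M(n + 1, L + 1), I(n + 1, L + 1), D(n + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG);
  std::fill(I.begin(), I.end(), NEG);
  std::fill(D.begin(), D.end(), NEG);
  double total = NEG;  // sum over exits; empty path added at the end
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= L; ++k) {
      double acc = 0.0;  // fresh entry contributes weight 1
      if (k >= 2) {
        acc = lse2(acc, M(i - 1, k - 1) + tb(k - 1, 0));
        acc = lse2(acc, I(i - 1, k - 1) + tb(k - 1, 3));
        acc = lse2(acc, D(i - 1, k - 1) + tb(k - 1, 5));
      }
      M(i, k) = msc(i - 1, k - 1) + acc;
      total = lse2(total, M(i, k));  // exit from M at zero cost
      if (k < L) {
        double a = lse2(M(i - 1, k) + tb(k, 1), I(i - 1, k) + tb(k, 4));
        I(i, k) = isc(i - 1, k - 1) + a;
      }
      if (k >= 2) {
        D(i, k) = lse2(M(i, k - 1) + tb(k - 1, 2),
                       D(i, k - 1) + tb(k - 1, 6));
      }
    }
  }
  return lse2(total, 0.0);  // include the empty alignment
}
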