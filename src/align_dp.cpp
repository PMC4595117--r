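// Profile-profile global alignment with affine, context-modulated gap costs.
//
// Cost semantics shared by all three entry points (the DP optimizer, the
// standalone path scorer, and the exhaustive enumerator used as a test
// oracle):
//   match i,j:            + S(i-1, j-1)
//   open gap in B while consuming A column i at B boundary j:
//       cost = tfac * (go - clamp(flankB[j] + runA[i-1], cf * go))
//   extend that gap:
//       cost = tfac * (ge - clamp(extA[i-1], cf * ge))
//   (symmetrically for gaps in A), where tfac = terminal_factor when the gap
//   run sits at boundary 0 or at the far end of the gapped profile, else 1.
// Modifiers are log-odds of gap likelihood (positive = gap favored), so they
// are subtracted from the base cost; the clamp enforces the +/- 20 % (by
// default) modulation contract.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e30;

static inline double clampv(double raw, double lim) {
  if (raw > lim) return lim;
  if (raw < -lim) return -lim;
  return raw;
}

struct GapCosts {
  const NumericVector &flankA, &flankB, &runA, &runB, &extA, &extB;
  double go, ge, tf, cf;
  int LA, LB;
  // open a gap in B (consume A column i, 1-based) at B boundary j (0..LB)
  double openB(int i, int j) const {
    double tfac = (j == 0 || j == LB) ? tf : 1.0;
    return tfac * (go - clampv(flankB[j] + runA[i - 1], cf * go));
  }
  double extB_(int i, int j) const {
    double tfac = (j == 0 || j == LB) ? tf : 1.0;
    return tfac * (ge - clampv(extA[i - 1], cf * ge));
  }
  double openA(int i, int j) const {
    double tfac = (i == 0 || i == LA) ? tf : 1.0;
    return tfac * (go - clampv(flankA[i] + runB[j - 1], cf * go));
  }
  double extA_(int i, int j) const {
    double tfac = (i == 0 || i == LA) ? tf : 1.0;
    return tfac * (ge - clampv(extB[j - 1], cf * ge));
  }
};

// [[Rcpp::export]]
List align_dp_cpp(NumericMatrix S,
                  NumericVector flankA, NumericVector flankB,
                  NumericVector runA, NumericVector runB,
                  NumericVector extA, NumericVector extB,
                  double gap_open, double gap_extend,
                  double terminal_factor, double clamp_fraction) {
  int LA = S.nrow(), LB = S.ncol();
  GapCosts gc{flankA, flankB, runA, runB, extA, extB,
              gap_open, gap_extend, terminal_factor, clamp_fraction, LA, LB};

  int W = LB + 1;
  std::vector<double> M((LA + 1) * W, NEG), X((LA + 1) * W, NEG),
      Y((LA + 1) * W, NEG);
  // traceback: for M, predecessor state; for X/Y, whether extended (1) or
  // opened from which state (0 = from M, 2 = from the other gap state)
  std::vector<signed char> tbM((LA + 1) * W, -1), tbX((LA + 1) * W, -1),
      tbY((LA + 1) * W, -1);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= LA; ++i) {
    double v = (i == 1) ? M[at(0, 0)] - gc.openB(1, 0)
                        : X[at(i - 1, 0)] - gc.extB_(i, 0);
    X[at(i, 0)] = v;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= LB; ++j) {
    double v = (j == 1) ? M[at(0, 0)] - gc.openA(0, 1)
                        : Y[at(0, j - 1)] - gc.extA_(0, j);
    Y[at(0, j)] = v;
    tbY[at(0, j)] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      // match: prefer M, then X, then Y on ties
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      double best = m0; signed char tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M[at(i, j)] = S(i - 1, j - 1) + best;
      tbM[at(i, j)] = tb;

      // gap in B (vertical, consume A col i)
      double op = gc.openB(i, j), ex = gc.extB_(i, j);
      double fromM = M[at(i - 1, j)] - op;
      double fromY = Y[at(i - 1, j)] - op;
      double fromX = X[at(i - 1, j)] - ex;
      best = fromM; tb = 0;
      if (fromX > best) { best = fromX; tb = 1; }
      if (fromY > best) { best = fromY; tb = 2; }
      X[at(i, j)] = best; tbX[at(i, j)] = tb;

      // gap in A (horizontal, consume B col j)
      op = gc.openA(i, j); ex = gc.extA_(i, j);
      fromM = M[at(i, j - 1)] - op;
      fromX = X[at(i, j - 1)] - op;
      double fromYe = Y[at(i, j - 1)] - ex;
      best = fromM; tb = 0;
      if (fromYe > best) { best = fromYe; tb = 1; }
      if (fromX > best) { best = fromX; tb = 2; }
      Y[at(i, j)] = best; tbY[at(i, j)] = tb;
    }
  }

  double sM = M[at(LA, LB)], sX = X[at(LA, LB)], sY = Y[at(LA, LB)];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  // traceback -> moves (1 = match, 2 = consume A / gap in B, 3 = consume B)
  std::vector<int> rev;
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tbM[at(i, j)];
      rev.push_back(1); --i; --j;
      state = tb;
    } else if (state == 1) {
      signed char tb = tbX[at(i, j)];
      rev.push_back(2); --i;
      state = (tb == 0) ? 0 : (tb == 1 ? 1 : 2);
    } else {
      signed char tb = tbY[at(i, j)];
      rev.push_back(3); --j;
      state = (tb == 0) ? 0 : (tb == 1 ? 2 : 1);
    }
  }
  IntegerVector moves(rev.size());
  for (size_t k = 0; k < rev.size(); ++k)
    moves[k] = rev[rev.size() - 1 - k];
  return List::create(_["score"] = score, _["moves"] = moves);
}

// score a complete move path from scratch (independent of the DP tables)
static double score_path_impl(const IntegerVector &moves, const NumericMatrix &S,
                              const GapCosts &gc) {
  double sc = 0.0;
  int i = 0, j = 0, prev = 0;
  for (int k = 0; k < moves.size(); ++k) {
    int mv = moves[k];
    if (mv == 1) {
      sc += S(i, j); ++i; ++j;
    } else if (mv == 2) {
      ++i;
      sc -= (prev == 2) ? gc.extB_(i, j) : gc.openB(i, j);
    } else {
      ++j;  // openA/extA_ take the A boundary (= i) and the consumed B column
      sc -= (prev == 3) ? gc.extA_(i, j) : gc.openA(i, j);
    }
    prev = mv;
  }
  return sc;
}

// [[Rcpp::export]]
double score_path_cpp(IntegerVector moves, NumericMatrix S,
                      NumericVector flankA, NumericVector flankB,
                      NumericVector runA, NumericVector runB,
                      NumericVector extA, NumericVector extB,
                      double gap_open, double gap_extend,
                      double terminal_factor, double clamp_fraction) {
  int LA = S.nrow(), LB = S.ncol();
  GapCosts gc{flankA, flankB, runA, runB, extA, extB,
              gap_open, gap_extend, terminal_factor, clamp_fraction, LA, LB};
  return score_path_impl(moves, S, gc);
}

static void enum_rec(int i, int j, int LA, int LB, std::vector<int> &buf,
                     const NumericMatrix &S, const GapCosts &gc,
                     double &best, double &count) {
  if (i == LA && j == LB) {
    IntegerVector mv(buf.begin(), buf.end());
    double sc = score_path_impl(mv, S, gc);
    if (sc > best) best = sc;
    count += 1.0;
    return;
  }
  if (i < LA && j < LB) {
    buf.push_back(1);
    enum_rec(i + 1, j + 1, LA, LB, buf, S, gc, best, count);
    buf.pop_back();
  }
  if (i < LA) {
    buf.push_back(2);
    enum_rec(i + 1, j, LA, LB, buf, S, gc, best, count);
    buf.pop_back();
  }
  if (j < LB) {
    buf.push_back(3);
    enum_rec(i, j + 1, LA, LB, buf, S, gc, best, count);
    buf.pop_back();
  }
}

// exhaustive enumeration of every global alignment; test oracle only
// [[Rcpp::export]]
List enum_align_cpp(NumericMatrix S,
                    NumericVector flankA, NumericVector flankB,
                    NumericVector runA, NumericVector runB,
                    NumericVector extA, NumericVector extB,
                    double gap_open, double gap_extend,
                    double terminal_factor, double clamp_fraction) {
  int LA = S.nrow(), LB = S.ncol();
  if (LA > 8 || LB > 8) stop("enumeration oracle is for tiny problems only");
  GapCosts gc{flankA, flankB, runA, runB, extA, extB,
              gap_open, gap_extend, terminal_factor, clamp_fraction, LA, LB};
  double best = NEG, count = 0.0;
  std::vector<int> buf;
  enum_rec(0, 0, LA, LB, buf, S, gc, best, count);
  return List::create(_["score"] = best, _["n_alignments"] = count);
}
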