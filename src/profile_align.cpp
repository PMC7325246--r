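#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two residue-count profiles (Gotoh).
//
// Profiles are 21 x L count matrices (rows = 20 standard residues + X,
// in the caller's fixed alphabet order); gap characters inside a profile
// simply do not contribute counts. Column-vs-column score is the
// sum-of-pairs substitution score averaged over the nA*nB sequence pairs,
// so the single-sequence case reduces exactly to the substitution score.
// A gap of length L costs gap_open + (L-1)*gap_extend.
//
// Tie-breaking on equal scores is fixed: diagonal (match/mismatch) is
// preferred over a gap in profile A (consuming a column of B), which is
// preferred over a gap in profile B.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix profA, IntegerMatrix profB,
                       NumericMatrix submat, double gap_open,
                       double gap_extend, int nA, int nB) {
  const int La = profA.ncol(), Lb = profB.ncol();
  const int nres = profA.nrow();  // 21

  // Pre-compute column-pair scores.
  NumericMatrix cs(La, Lb);
  for (int i = 0; i < La; ++i) {
    for (int j = 0; j < Lb; ++j) {
      double s = 0.0;
      for (int r = 0; r < nres; ++r) {
        const int ar = profA(r, i);
        if (ar == 0) continue;
        for (int q = 0; q < nres; ++q) {
          const int bq = profB(q, j);
          if (bq == 0) continue;
          s += (double)ar * bq * submat(r, q);
        }
      }
      cs(i, j) = s / ((double)nA * nB);
    }
  }

  // DP matrices: M diagonal, X gap in B (consumes A), Y gap in A (consumes B).
  NumericMatrix M(La + 1, Lb + 1), X(La + 1, Lb + 1), Y(La + 1, Lb + 1);
  IntegerMatrix pM(La + 1, Lb + 1), pX(La + 1, Lb + 1), pY(La + 1, Lb + 1);
  // pointer codes: 0 = from M, 1 = from Y (gap in A), 2 = from X (gap in B)

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= La; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
    pX(i, 0) = (i == 1) ? 0 : 2;
  }
  for (int j = 1; j <= Lb; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
    pY(0, j) = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      // M: consume a_i and b_j. Tie order: M >= Y >= X.
      double best = M(i - 1, j - 1);
      int ptr = 0;
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); ptr = 1; }
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); ptr = 2; }
      M(i, j) = best + cs(i - 1, j - 1);
      pM(i, j) = ptr;

      // X: gap in B, consume a_i (vertical).
      double open = M(i - 1, j) - gap_open;
      double openY = Y(i - 1, j) - gap_open;
      double ext = X(i - 1, j) - gap_extend;
      best = open; ptr = 0;
      if (openY > best) { best = openY; ptr = 1; }
      if (ext > best) { best = ext; ptr = 2; }
      X(i, j) = best;
      pX(i, j) = ptr;

      // Y: gap in A, consume b_j (horizontal).
      open = M(i, j - 1) - gap_open;
      double openX = X(i, j - 1) - gap_open;
      ext = Y(i, j - 1) - gap_extend;
      best = open; ptr = 0;
      if (openX > best) { best = openX; ptr = 2; }
      if (ext > best) { best = ext; ptr = 1; }
      Y(i, j) = best;
      pY(i, j) = ptr;
    }
  }

  // Terminal state: prefer M, then Y, then X on ties.
  double score = M(La, Lb);
  int state = 0;
  if (Y(La, Lb) > score) { score = Y(La, Lb); state = 1; }
  if (X(La, Lb) > score) { score = X(La, Lb); state = 2; }

  // Traceback: build op string, 'M' both, 'A' = gap in A (consume B),
  // 'B' = gap in B (consume A).
  std::string ops;
  ops.reserve(La + Lb);
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('M');
      state = pM(i, j);
      --i; --j;
    } else if (state == 1) {  // Y: gap in A
      ops.push_back('A');
      state = pY(i, j);
      --j;
    } else {  // X: gap in B
      ops.push_back('B');
      state = pX(i, j);
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops);
}
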