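#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap of length k costs gap_open + k * gap_extend
// (BLAST convention: existence 11 + per-residue 1 under BLOSUM62 defaults).
// Sequences arrive as 0-based integer codes into the substitution matrix.

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Score-only banded-memory DP: O(n) memory, used for bulk database scans.
// [[Rcpp::export]]
double sw_score_cpp(const IntegerVector& q, const IntegerVector& t,
                    const NumericMatrix& submat,
                    double gap_open, double gap_extend) {
  const int m = q.size(), n = t.size();
  const double goe = gap_open + gap_extend;
  std::vector<double> M(n + 1, 0.0), Iy(n + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diagM = 0.0, diagIy = R_NegInf, diagIx = R_NegInf;
    double Ix = R_NegInf;
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      double upM = M[j], upIy = Iy[j];
      double m_new = max3(diagM, diagIx, diagIy) + submat(qi, t[j - 1]);
      if (m_new < 0.0) m_new = 0.0;
      double iy_new = std::max(upM - goe, upIy - gap_extend);
      // Ix: gap in target, consumes query column j-1's M of this row
      double ix_new = std::max(M[j - 1] - goe, Ix - gap_extend);
      // careful: M[j-1] at this point already holds row i's value
      diagM = upM; diagIy = upIy; diagIx = Ix;
      M[j] = m_new; Iy[j] = iy_new; Ix = ix_new;
      if (m_new > best) best = m_new;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_block_cpp(const IntegerVector& q, const List& targets,
                                 const NumericMatrix& submat,
                                 double gap_open, double gap_extend) {
  const int k = targets.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s) {
    IntegerVector t = targets[s];
    out[s] = sw_score_cpp(q, t, submat, gap_open, gap_extend);
  }
  return out;
}

// Full DP with traceback: returns the optimal local alignment footprint,
// match count and aligned column count (gap columns included).
// [[Rcpp::export]]
List sw_align_cpp(const IntegerVector& q, const IntegerVector& t,
                  const NumericMatrix& submat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = t.size();
  const double goe = gap_open + gap_extend;
  const double NEG = -1e18;
  // state matrices (m+1) x (n+1); flat index i*(n+1)+j
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> Ix((m + 1) * (n + 1), NEG);
  std::vector<double> Iy((m + 1) * (n + 1), NEG);
  // traceback codes: for M, which predecessor state fed the diagonal
  // 0 = start (score reset), 1 = M, 2 = Ix, 3 = Iy
  std::vector<signed char> tbM((m + 1) * (n + 1), 0);
  std::vector<signed char> tbIx((m + 1) * (n + 1), 0); // 1 = from M, 2 = from Ix
  std::vector<signed char> tbIy((m + 1) * (n + 1), 0); // 1 = from M, 3 = from Iy
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int dg = (i - 1) * (n + 1) + (j - 1);
      const int up = (i - 1) * (n + 1) + j;
      const int lf = i * (n + 1) + (j - 1);
      const double s = submat(qi, t[j - 1]);
      double dM = M[dg] + s, dIx = Ix[dg] + s, dIy = Iy[dg] + s;
      double mval = 0.0; signed char mtb = 0;
      if (dM > mval)  { mval = dM;  mtb = 1; }
      if (dIx > mval) { mval = dIx; mtb = 2; }
      if (dIy > mval) { mval = dIy; mtb = 3; }
      M[idx] = mval; tbM[idx] = mtb;
      double ixM = M[lf] - goe, ixX = Ix[lf] - gap_extend;
      if (ixM >= ixX) { Ix[idx] = ixM; tbIx[idx] = 1; }
      else            { Ix[idx] = ixX; tbIx[idx] = 2; }
      double iyM = M[up] - goe, iyY = Iy[up] - gap_extend;
      if (iyM >= iyY) { Iy[idx] = iyM; tbIy[idx] = 1; }
      else            { Iy[idx] = iyY; tbIy[idx] = 3; }
      if (mval > best) { best = mval; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["t_start"] = NA_INTEGER, _["t_end"] = NA_INTEGER,
                        _["matches"] = 0, _["columns"] = 0);
  }
  // traceback from (bi, bj) in state M until the local alignment start
  int i = bi, j = bj, state = 1;
  int matches = 0, columns = 0;
  int q_start = bi, t_start = bj;
  while (true) {
    const int idx = i * (n + 1) + j;
    if (state == 1) {
      signed char tb = tbM[idx];
      columns++;
      if (q[i - 1] == t[j - 1]) matches++;
      q_start = i; t_start = j;
      if (tb == 0) break;
      i--; j--;
      if (tb == 1) {
        // an empty (zero-score) prefix means the alignment starts here
        if (M[i * (n + 1) + j] <= 0.0) break;
        state = 1;
      } else {
        state = tb;
      }
    } else if (state == 2) { // Ix consumes target residues (gap in query)
      columns++;
      signed char tb = tbIx[idx];
      j--;
      state = (tb == 1) ? 1 : 2;
    } else {                 // Iy consumes query residues (gap in target)
      columns++;
      signed char tb = tbIy[idx];
      i--;
      state = (tb == 1) ? 1 : 3;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = bi,
                      _["t_start"] = t_start, _["t_end"] = bj,
                      _["matches"] = matches, _["columns"] = columns);
}
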