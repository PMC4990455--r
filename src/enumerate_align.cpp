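#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of all global alignments (no double-gap columns)
// of two residue-index sequences, scoring each with an affine cost model in
// which a gap run of length k costs open + (k - 1) * extend. Terminal gaps
// are charged unless penalize_ends is false. Exponential in the sequence
// lengths; meant as a brute-force reference for short sequences.

static double best;

// state: 0 = none/diagonal, 1 = gap in b (a consumed), 2 = gap in a
static void rec(const IntegerVector& a, const IntegerVector& b,
                const NumericMatrix& sm, double open, double ext,
                bool penalize_ends, int i, int j, int state, double sc) {
  int m = a.size(), n = b.size();
  if (i == m && j == n) {
    if (sc > best) best = sc;
    return;
  }
  if (i < m && j < n) {
    rec(a, b, sm, open, ext, penalize_ends, i + 1, j + 1, 0,
        sc + sm(a[i], b[j]));
  }
  if (i < m) { // a[i] against a gap in b
    bool terminal = (j == 0 || j == n);
    double g = (state == 1) ? ext : open;
    if (terminal && !penalize_ends) g = 0.0;
    rec(a, b, sm, open, ext, penalize_ends, i + 1, j, 1, sc + g);
  }
  if (j < n) { // gap in a against b[j]
    bool terminal = (i == 0 || i == m);
    double g = (state == 2) ? ext : open;
    if (terminal && !penalize_ends) g = 0.0;
    rec(a, b, sm, open, ext, penalize_ends, i, j + 1, 2, sc + g);
  }
}

// [[Rcpp::export]]
double enumerate_align_score(IntegerVector a, IntegerVector b,
                             NumericMatrix sm, double gap_open,
                             double gap_extend, bool penalize_ends) {
  if (a.size() + b.size() > 40)
    stop("enumeration oracle limited to short sequences");
  if (a.size() == 0 && b.size() == 0) return 0.0;
  if (a.size() == 0 || b.size() == 0) {
    int k = std::max(a.size(), b.size());
    return penalize_ends ? gap_open + (k - 1) * gap_extend : 0.0;
  }
  best = R_NegInf;
  rec(a, b, sm, gap_open, gap_extend, penalize_ends, 0, 0, 0, 0.0);
  return best;
}
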