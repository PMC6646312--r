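#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric subsample of one column, by a sequential
// hypergeometric walk over cells: draws for cell i condition on what the
// remaining cells still hold.  Uses R's RNG so results are reproducible
// under set.seed().
static void rarefy_one(const int *x, int *out, int n, double depth) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  double remaining = total, want = depth;
  for (int i = 0; i < n; ++i) {
    if (want <= 0) { out[i] = 0; continue; }
    double white = x[i], black = remaining - white;
    double drawn;
    if (black <= 0) {
      drawn = want; // only this cell is left
    } else if (white <= 0) {
      drawn = 0;
    } else {
      drawn = ::Rf_rhyper(white, black, want);
    }
    out[i] = (int) drawn;
    want -= drawn;
    remaining -= white;
  }
}

// [[Rcpp::export]]
IntegerVector rarefy_vector_cpp(IntegerVector x, int depth) {
  IntegerVector out(x.size());
  rarefy_one(INTEGER(x), INTEGER(out), x.size(), depth);
  return out;
}

// Rarefy every column of a species x samples matrix to its own depth.
// [[Rcpp::export]]
IntegerMatrix rarefy_columns_cpp(IntegerMatrix m, IntegerVector depths) {
  int nr = m.nrow(), nc = m.ncol();
  if (depths.size() != nc) stop("depths must have one entry per column");
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    rarefy_one(&m(0, j), &out(0, j), nr, depths[j]);
  }
  return out;
}
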