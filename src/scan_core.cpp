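#include <Rcpp.h>
using namespace Rcpp;

// Maximum matching-run score over allowed sequence pairs, for each
// permutation of the polymorphic-site columns. States are integers 1..4
// (0 = missing); a site supports a run only when both states are present
// and equal, any mismatch or missing state terminates the run.
//
// states: nseq x nsites, pairs: npairs x 2 (1-based row indices),
// perms: nperm x nsites (1-based column orders).
// [[Rcpp::export(name = ".perm_max_run")]]
NumericVector perm_max_run(const IntegerMatrix& states,
                           const IntegerMatrix& pairs,
                           const IntegerMatrix& perms) {
  const int nperm = perms.nrow();
  const int nsite = states.ncol();
  const int npair = pairs.nrow();
  if (perms.ncol() != nsite) stop("perms must have one column per site");
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    int best = 0;
    for (int q = 0; q < npair; ++q) {
      const int i = pairs(q, 0) - 1;
      const int j = pairs(q, 1) - 1;
      int run = 0;
      for (int c = 0; c < nsite; ++c) {
        const int col = perms(p, c) - 1;
        const int a = states(i, col);
        if (a > 0 && a == states(j, col)) {
          if (++run > best) best = run;
        } else {
          run = 0;
        }
      }
    }
    out[p] = best;
  }
  return out;
}
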