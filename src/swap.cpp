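#include <Rcpp.h>
using namespace Rcpp;

// Attempted 2x2 checkerboard swaps on a binary matrix. Each attempt picks a
// random pair of rows and a random pair of columns; when the 2x2 submatrix
// is a checkerboard it is flipped, which preserves both row and column sums.
// Uses R's RNG, so results follow set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_swap_chain(IntegerMatrix m, double n_attempts) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2) return out;
  for (double k = 0; k < n_attempts; k++) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      out(r1, c1) = 0; out(r2, c2) = 0; out(r1, c2) = 1; out(r2, c1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      out(r1, c1) = 1; out(r2, c2) = 1; out(r1, c2) = 0; out(r2, c1) = 0;
    }
  }
  return out;
}

// Number of distinct 2x2 checkerboard submatrices (used to detect frozen
// matrices that the swap chain cannot move).

// [[Rcpp::export]]
double cpp_n_checkerboards(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  double count = 0;
  for (int r1 = 0; r1 < nr - 1; r1++)
    for (int r2 = r1 + 1; r2 < nr; r2++)
      for (int c1 = 0; c1 < nc - 1; c1++)
        for (int c2 = c1 + 1; c2 < nc; c2++) {
          int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
          if ((a == 1 && d == 1 && b == 0 && c == 0) ||
              (a == 0 && d == 0 && b == 1 && c == 1))
            count += 1;
        }
  return count;
}
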