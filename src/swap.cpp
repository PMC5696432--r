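#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap (checkerboard) randomization of a binary matrix.
// Repeatedly draws two rows and two columns; if the 2x2 submatrix is a
// checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) it is flipped, which leaves
// every row and column sum unchanged.  Performs n_swaps *successful* swaps;
// gives up (flag) after max_fail consecutive failed draws, which only happens
// when no checkerboard exists or the matrix is pathologically dense.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".swap_chain")]]
List swap_chain(IntegerMatrix m, int n_swaps, int max_fail) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  int done = 0;
  int fails = 0;
  if (nr < 2 || nc < 2)
    return List::create(_["matrix"] = x, _["swaps_done"] = 0,
                        _["gave_up"] = (n_swaps > 0));
  while (done < n_swaps && fails < max_fail) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      x(r1, c1) = 0; x(r2, c2) = 0; x(r1, c2) = 1; x(r2, c1) = 1;
      done++; fails = 0;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      x(r1, c1) = 1; x(r2, c2) = 1; x(r1, c2) = 0; x(r2, c1) = 0;
      done++; fails = 0;
    } else {
      fails++;
    }
  }
  return List::create(_["matrix"] = x, _["swaps_done"] = done,
                      _["gave_up"] = (done < n_swaps));
}
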