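#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG stream.
static inline int runif_int(int n) {
  int k = (int)(n * unif_rand());
  return (k == n) ? n - 1 : k;
}

// Swap chain: apply n_itr successful checkerboard swaps, sampling 2x2
// submatrices uniformly and skipping non-checkerboards without counting.
// The caller guarantees at least one checkerboard exists (otherwise the
// chain cannot move and the guard trips).
// [[Rcpp::export]]
IntegerMatrix swap_chain_cpp(const IntegerMatrix& m, int n_itr) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2) return out;
  int done = 0;
  long long proposals = 0;
  const long long guard = 2000000000LL;
  while (done < n_itr) {
    int r1 = runif_int(nr);
    int r2 = runif_int(nr - 1);
    if (r2 >= r1) ++r2;
    int c1 = runif_int(nc);
    int c2 = runif_int(nc - 1);
    if (c2 >= c1) ++c2;
    const int a = out(r1, c1);
    if (a != out(r1, c2) && out(r2, c1) != a && out(r2, c2) == a) {
      out(r1, c1) = 1 - a;
      out(r1, c2) = a;
      out(r2, c1) = a;
      out(r2, c2) = 1 - a;
      ++done;
    }
    if (++proposals > guard) stop("swap chain stalled: no accepted swap");
  }
  return out;
}

// Curveball chain: each of the n_itr iterations draws two distinct rows
// and redistributes their exclusive species uniformly at random,
// preserving both row counts (a no-op when one row's set contains the
// other's).
// [[Rcpp::export]]
IntegerMatrix curveball_chain_cpp(const IntegerMatrix& m, int n_itr) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  if (nr < 2) return out;
  std::vector<int> pool;
  pool.reserve(nc);
  for (int it = 0; it < n_itr; ++it) {
    int r1 = runif_int(nr);
    int r2 = runif_int(nr - 1);
    if (r2 >= r1) ++r2;
    pool.clear();
    int n1 = 0;
    for (int j = 0; j < nc; ++j) {
      const int x = out(r1, j), y = out(r2, j);
      if (x == 1 && y == 0) {
        pool.push_back(j);
        ++n1;
      } else if (x == 0 && y == 1) {
        pool.push_back(j);
      }
    }
    const int n = (int)pool.size();
    if (n1 == 0 || n1 == n) continue;
    // partial Fisher-Yates: the first n1 entries go to row r1
    for (int i = 0; i < n1; ++i) {
      const int k = i + runif_int(n - i);
      std::swap(pool[i], pool[k]);
    }
    for (int i = 0; i < n; ++i) {
      out(r1, pool[i]) = (i < n1) ? 1 : 0;
      out(r2, pool[i]) = (i < n1) ? 0 : 1;
    }
  }
  return out;
}
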