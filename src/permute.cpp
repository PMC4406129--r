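#include <Rcpp.h>
using namespace Rcpp;

// Serial checkerboard-swap chain on a binary group-by-individual matrix.
// A proposal picks two events (rows) and two individuals (columns) uniformly
// at random; if the 2x2 submatrix is a checkerboard (each individual in
// exactly one of the two events) the occurrences are exchanged. Row and
// column sums are conserved by construction. When strata are supplied the
// second event is drawn from the first event's stratum, keeping the proposal
// symmetric and swaps within strata.
// [[Rcpp::export]]
IntegerMatrix gbi_swap_chain_cpp(IntegerMatrix gbi, IntegerVector strata,
                                 int n_accept) {
  IntegerMatrix g = clone(gbi);
  const int nr = g.nrow(), nc = g.ncol();
  const bool use_strata = strata.size() > 0;

  std::vector< std::vector<int> > by_stratum;
  if (use_strata) {
    int ns = 0;
    for (int i = 0; i < nr; ++i) ns = std::max(ns, strata[i] + 1);
    by_stratum.resize(ns);
    for (int i = 0; i < nr; ++i) by_stratum[strata[i]].push_back(i);
  }

  const long long max_tries = 2000000LL;
  long long tries = 0;
  int accepted = 0;
  while (accepted < n_accept) {
    if (++tries > max_tries)
      stop("no legal swap found after %lld proposals: degenerate GBI "
           "(or strata too fine)", max_tries);
    int e1 = (int)(unif_rand() * nr);
    int e2;
    if (use_strata) {
      const std::vector<int>& peers = by_stratum[strata[e1]];
      e2 = peers[(int)(unif_rand() * peers.size())];
    } else {
      e2 = (int)(unif_rand() * nr);
    }
    if (e1 == e2) continue;
    int i1 = (int)(unif_rand() * nc);
    int i2 = (int)(unif_rand() * nc);
    if (i1 == i2) continue;
    if (g(e1, i1) == 1 && g(e2, i2) == 1 &&
        g(e1, i2) == 0 && g(e2, i1) == 0) {
      g(e1, i1) = 0; g(e2, i2) = 0;
      g(e1, i2) = 1; g(e2, i1) = 1;
      ++accepted;
      tries = 0;
    }
  }
  return g;
}
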