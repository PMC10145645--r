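#include <Rcpp.h>
using namespace Rcpp;

// Markov scanpath chain over the 10 AOI states, drawn from R's RNG so a
// fixed R seed reproduces the chain exactly.

// [[Rcpp::export(name = ".sim_chain_cpp")]]
IntegerVector sim_chain_cpp(NumericMatrix P, NumericVector init, int n) {
  const int S = init.size();
  IntegerVector states(n);
  // cumulative rows once
  std::vector<double> cum(S * S);
  for (int i = 0; i < S; ++i) {
    double acc = 0.0;
    for (int j = 0; j < S; ++j) {
      acc += P(i, j);
      cum[i * S + j] = acc;
    }
  }
  std::vector<double> cinit(S);
  double acc = 0.0;
  for (int j = 0; j < S; ++j) { acc += init[j]; cinit[j] = acc; }

  double u = unif_rand() * cinit[S - 1];
  int s = 0;
  while (s < S - 1 && u > cinit[s]) ++s;
  states[0] = s + 1;
  for (int k = 1; k < n; ++k) {
    const double* row = &cum[s * S];
    u = unif_rand() * row[S - 1];
    int t = 0;
    while (t < S - 1 && u > row[t]) ++t;
    states[k] = t + 1;
    s = t;
  }
  return states;
}
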