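#include <Rcpp.h>
using namespace Rcpp;

// Nussinov-style minimum-energy folding over a base-pair energy model.
// code: 1=A,2=C,3=G,4=U, 0=unpairable (N); etab: 4x4 pair energies with
// NA for non-pairing combinations; min_loop: minimum hairpin loop length.
// Traceback prefers leaving the 3' base unpaired, then the 5'-most
// partner, matching the reference R implementation.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector code, NumericMatrix etab, int min_loop) {
  int n = code.size();
  NumericMatrix E(n, n);
  IntegerMatrix choice(n, n);
  if (n > min_loop + 1) {
    for (int len = min_loop + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double best = E(i, j - 1);
        int bestk = -1;
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (code[k] == 0 || code[j] == 0) continue;
          double e = etab(code[k] - 1, code[j] - 1);
          if (NumericMatrix::is_na(e)) continue;
          double v = e;
          if (k > i) v += E(i, k - 1);
          if (k + 1 <= j - 1) v += E(k + 1, j - 1);
          if (v < best - 1e-12) { best = v; bestk = k; }
        }
        E(i, j) = best;
        choice(i, j) = bestk;
      }
    }
  }
  // traceback
  IntegerVector pairing(n, 0);  // 1-based partner, 0 = unpaired
  int n_paired = 0;
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int k = choice(i, j);
    if (k < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      pairing[k] = j + 1;
      pairing[j] = k + 1;
      n_paired += 2;
      if (k > i) stack.push_back(std::make_pair(i, k - 1));
      if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
    }
  }
  double mfe = (n > min_loop + 1) ? E(0, n - 1) : 0.0;
  return List::create(_["mfe"] = mfe, _["n_paired"] = n_paired,
                      _["pairing"] = pairing);
}
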