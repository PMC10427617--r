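#include <Rcpp.h>
using namespace Rcpp;

// Post-order pruning pass. `edge` is the tree's edge matrix in postorder,
// `Pm` holds vec(P(t_e)) (column-major) per edge row, `Ltips` the tip
// likelihood matrix. Returns scaled partials, per-node accumulated log
// scalers, and the per-edge child-lifted vectors needed by the marginal
// (above-partial) pass.
// [[Rcpp::export]]
List pruning_core(IntegerMatrix edge, NumericMatrix Pm, NumericMatrix Ltips,
                  int nnode) {
  const int nt = Ltips.nrow(), k = Ltips.ncol();
  const int N = nt + nnode, ne = edge.nrow();
  NumericMatrix part(N, k), vmat(ne, k);
  NumericVector logsc(N);
  for (int i = 0; i < nt; i++)
    for (int j = 0; j < k; j++) part(i, j) = Ltips(i, j);
  for (int i = nt; i < N; i++)
    for (int j = 0; j < k; j++) part(i, j) = 1.0;
  for (int e = 0; e < ne; e++) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int i = 0; i < k; i++) {
      double s = 0.0;
      for (int j = 0; j < k; j++) s += Pm(e, i + j * k) * part(c, j);
      vmat(e, i) = s;
    }
    double mx = 0.0;
    for (int i = 0; i < k; i++) {
      part(p, i) *= vmat(e, i);
      if (part(p, i) > mx) mx = part(p, i);
    }
    logsc[p] += logsc[c];
    if (mx > 0.0 && mx < 1e-50) {
      for (int i = 0; i < k; i++) part(p, i) /= mx;
      logsc[p] += std::log(mx);
    }
  }
  return List::create(_["part"] = part, _["logsc"] = logsc,
                      _["vmat"] = vmat);
}
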