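#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Minimum-cost rectangular assignment (Hungarian algorithm, shortest
// augmenting paths with potentials). Requires nrow(cost) <= ncol(cost);
// every row is assigned to a distinct column. O(n^2 m). Deterministic:
// ties are broken by the lowest column index.
// [[Rcpp::export]]
List lap_min(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n == 0) {
    return List::create(_["assignment"] = IntegerVector(0), _["value"] = 0.0);
  }
  if (n > m) stop("lap_min: cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector assignment(n);
  double value = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (p[j]) {
      assignment[p[j] - 1] = j;
      value += cost(p[j] - 1, j - 1);
    }
  }
  return List::create(_["assignment"] = assignment, _["value"] = value);
}
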