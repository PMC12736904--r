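#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ARC rule: connect i -> j (j > i) iff the chord angle
// theta_ij = atan((x[j] - x[i]) / (j - i)) strictly exceeds theta_ik for
// every intermediate k. Adjacent pairs connect vacuously. atan is strictly
// increasing, so comparisons are done on slopes; theta is reported per edge.

// O(n^2) sweep: for each source i scan j upward keeping the running maximum
// of the slope to all points seen so far (the candidates for intermediate k).
// [[Rcpp::export(name = ".arc_edges_sweep")]]
List arc_edges_sweep(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 samples");
  std::vector<int> from, to;
  std::vector<double> theta;
  from.reserve(2 * n);
  to.reserve(2 * n);
  theta.reserve(2 * n);
  for (int i = 0; i < n - 1; ++i) {
    double best = R_NegInf;  // max slope i -> k over k in (i, j)
    for (int j = i + 1; j < n; ++j) {
      const double slope = (x[j] - x[i]) / double(j - i);
      if (j == i + 1 || slope > best) {
        from.push_back(i);
        to.push_back(j);
        theta.push_back(std::atan(slope));
      }
      if (slope > best) best = slope;
    }
  }
  return List::create(_["i"] = wrap(from), _["j"] = wrap(to),
                      _["theta"] = wrap(theta));
}

// Literal O(n^3) transcription of the angular monotonicity condition,
// checking atan-ed angles pair by pair over every intermediate index.
// Reference oracle; intended for n up to a few hundred.
// [[Rcpp::export(name = ".arc_edges_brute")]]
List arc_edges_brute(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 samples");
  std::vector<int> from, to;
  std::vector<double> theta;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double theta_ij = std::atan((x[j] - x[i]) / double(j - i));
      bool ok = true;
      for (int k = i + 1; k < j; ++k) {
        const double theta_ik = std::atan((x[k] - x[i]) / double(k - i));
        if (!(theta_ik < theta_ij)) { ok = false; break; }
      }
      if (ok) {
        from.push_back(i);
        to.push_back(j);
        theta.push_back(theta_ij);
      }
    }
  }
  return List::create(_["i"] = wrap(from), _["j"] = wrap(to),
                      _["theta"] = wrap(theta));
}
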